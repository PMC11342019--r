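variable_id,variable,n_including,extraction_rate,accuracy
1,Date the injury event occurred,800,99.26,90.65
2,Geographic location where the injury event occurred,808,98.54,88.60
3,Type of place where the injury event occurred,811,99.75,80.52
4,Nature (type) of injury,837,99.52,85.07
5,Body part injured,826,99.52,80.75
6,External cause of injury,810,99.75,79.75
7,Clinical diagnosis of injury,174,19.68,44.94
8.1,Number of deaths,412,50.80,78.81
8.2,Number of injured persons,547,66.46,83.96
8.3,Number of child deaths,381,46.98,81.41
8.4,Number of injured children,554,66.99,92.02
9,Number of involved products,818,98.44,83.41
10,Product name,825,98.92,79.11
11,Brand name of product,NA,NA,NA
12,Characteristics of product,27,3.23,62.77
13,Type of product,829,99.16,70.76
14,Disposition of injury,811,99.51,84.71
15,Number of involved children,800,99.38,78.25
16,Age of injured child,665,81.80,87.52
17,Sex of injured child,793,99.50,84.11
18,Activity of child(ren) as injury happened,827,99.52,76.90
19,Number of supervisors,207,24.76,70.14
20,Age of supervisor,98,12.34,87.33
21,Sex of supervisor,817,99.51,77.11
22,Supervisor of the injured child,644,78.54,73.77
23,Whether the supervisor was physically with the child,829,99.40,83.72
24.1,Human-related etiological factor,834,96.64,86.50
24.2,Product-related etiological factor,740,86.25,89.94
24.3,Description of the detailed etiological factor,698,77.64,4.81
25,Weather conditions,NA,NA,NA
26,Air quality,NA,NA,NA
27,Temperature,NA,NA,NA
28,Other adverse environmental conditions,NA,NA,NA
29,Product-related preventive measure,377,48.33,36.73
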