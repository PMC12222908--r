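population	locus	allele	frequency
PopW	A	A*01:01	0.251
PopW	A	A*02:01	0.2911
PopW	A	A*03:01	0.086
PopW	A	A*04:01	0.0756
PopW	A	A*05:01	0.1497
PopW	A	A*06:01	0.1106
PopW	A	A*07:01	0.0081
PopW	A	A*08:01	0.0279
PopX	A	A*01:01	0.1548
PopX	A	A*02:01	0.0146
PopX	A	A*03:01	0.4231
PopX	A	A*04:01	0.2628
PopX	A	A*05:01	0.049
PopX	A	A*06:01	0.0569
PopX	A	A*07:01	0.0122
PopX	A	A*08:01	0.0266
PopY	A	A*01:01	0.6293
PopY	A	A*02:01	0.2739
PopY	A	A*03:01	0.0468
PopY	A	A*04:01	0.0017
PopY	A	A*05:01	6e-04
PopY	A	A*06:01	0.0127
PopY	A	A*07:01	0.0296
PopY	A	A*08:01	0.0054
PopZ	A	A*01:01	0.1776
PopZ	A	A*02:01	0.0541
PopZ	A	A*03:01	0.0422
PopZ	A	A*04:01	0.3464
PopZ	A	A*05:01	0.0455
PopZ	A	A*06:01	0.031
PopZ	A	A*07:01	0.2149
PopZ	A	A*08:01	0.0883
PopW	B	B*01:01	0.2165
PopW	B	B*02:01	0.2212
PopW	B	B*03:01	0.1711
PopW	B	B*04:01	0.0937
PopW	B	B*05:01	0.0255
PopW	B	B*06:01	0.0802
PopW	B	B*07:01	0.0231
PopW	B	B*08:01	0.1203
PopW	B	B*09:01	0.0129
PopW	B	B*10:01	0.0355
PopX	B	B*01:01	0.1447
PopX	B	B*02:01	0.4078
PopX	B	B*03:01	0.037
PopX	B	B*04:01	0.1357
PopX	B	B*05:01	0.0504
PopX	B	B*06:01	0.0529
PopX	B	B*07:01	0.1126
PopX	B	B*08:01	0.001
PopX	B	B*09:01	0.0145
PopX	B	B*10:01	0.0434
PopY	B	B*01:01	0.1364
PopY	B	B*02:01	0.0031
PopY	B	B*03:01	0.0367
PopY	B	B*04:01	0.2288
PopY	B	B*05:01	0.0759
PopY	B	B*06:01	0.1499
PopY	B	B*07:01	0.1577
PopY	B	B*08:01	0.0861
PopY	B	B*09:01	0.0301
PopY	B	B*10:01	0.0953
PopZ	B	B*01:01	0.3024
PopZ	B	B*02:01	0.0215
PopZ	B	B*03:01	0.1085
PopZ	B	B*04:01	0.0719
PopZ	B	B*05:01	0.197
PopZ	B	B*06:01	0.0471
PopZ	B	B*07:01	0.0188
PopZ	B	B*08:01	0.2014
PopZ	B	B*09:01	0.0203
PopZ	B	B*10:01	0.0111
PopW	C	C*01:01	0.0725
PopW	C	C*02:01	0.3933
PopW	C	C*03:01	0.4376
PopW	C	C*04:01	0.0198
PopW	C	C*05:01	0.0062
PopW	C	C*06:01	0.0706
PopX	C	C*01:01	0.0282
PopX	C	C*02:01	0.2767
PopX	C	C*03:01	0.0468
PopX	C	C*04:01	0.2909
PopX	C	C*05:01	0.2313
PopX	C	C*06:01	0.1261
PopY	C	C*01:01	0.1407
PopY	C	C*02:01	0.1563
PopY	C	C*03:01	0.0022
PopY	C	C*04:01	0.2456
PopY	C	C*05:01	0.2975
PopY	C	C*06:01	0.1577
PopZ	C	C*01:01	0.1694
PopZ	C	C*02:01	0.132
PopZ	C	C*03:01	0.5379
PopZ	C	C*04:01	0.0345
PopZ	C	C*05:01	0.0134
PopZ	C	C*06:01	0.1128
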