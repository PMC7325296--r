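province_id,province_name,hdi_category
1,Sistan and Baluchestan,low
2,Kurdistan,low
3,North Khorasan,low
4,South Khorasan,low
5,West Azerbaijan,low
6,Ardebil,low
7,Hormozgan,low
8,Zanjan,low
9,Hamadan,low
10,Golestan,low
11,Kerman,low
12,Razavi Khorasan,middle
13,Lorestan,middle
14,East Azerbaijan,middle
15,Markazi,middle
16,Kohgiluyeh and Buyer-Ahmad,middle
17,Kermanshah,middle
18,Chahar Mahall and Bakhtiari,middle
19,Qazvin,middle
20,Khuzestan,middle
21,Gilan,middle
22,Fars,high
23,Bushehr,high
24,Ilam,high
25,Qom,high
26,Semnan,high
27,Yazd,high
28,Mazandaran,high
29,Esfahan,high
30,Tehran,high
31,Alborz,high
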