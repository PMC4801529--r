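sample_id,latin_name,pinyin,bitterness_mean,bitterness_sd,pH,excluded_by_study
1,CLEMATIDIS ARMANDII CAULIS,Chuanmutong,0.70,0.24,6.71,0
2,MORI RAMULUS,Sangzhi,0.67,0.23,6.57,0
3,UNCARIAE RAMULUS CUM UNCIS,Gouteng,0.70,0.25,6.72,0
4,PLANTAGINIS SEMEN,Cheqianzi,0.71,0.20,5.82,0
5,BAMBUSAE CAULIS IN TAENIAS,Zhuru,1.24,0.38,6.80,0
6,CHANGII RADIX,Mingdangshen,0.73,0.30,6.45,0
7,LYCOPI HERBA,Zelan,1.19,0.62,6.20,0
8,PORIA,Fuling,0.63,0.17,6.74,0
9,TETRAPANACIS MEDULLA,Tongcao,0.64,0.14,7.15,0
10,XANTHII FRUCTUS,Cang'erzi,1.21,0.50,6.81,0
11,EUCOMMIAE CORTEX,Duzhong,1.26,0.57,6.15,0
12,ALISMATIS RHIZOMA,Zexie,0.95,0.50,7.14,0
13,PLANTAGINIS HERBA,Cheqiancao,1.26,0.62,5.46,0
14,FRITILLARIAE THUNBERGII BULBUS,Zhebeimu,1.82,0.39,6.10,0
15,TRICHOSANTHIS RADIX,Tianhuafeng,0.91,0.36,6.55,0
16,RUBIAE RADIX ET RHIZOMA,Qiancao,1.81,0.66,5.83,0
17,CYNANCHI ATRATI RADIX ET RHIZOMA,Baiwei,1.67,0.62,5.91,0
18,LEONURI HERBA,Yimucao,2.54,0.84,6.09,1
19,CORYDALIS RHIZOMA,Yanhusuo,2.80,0.40,6.59,0
20,STEPHANIAE TETRANDRAE RADIX,Fangji,3.01,0.42,6.76,0
21,SCUTELLARIAE RADIX,Huangqin,3.28,0.53,5.36,0
22,MENISPERMI RHIZOMA,Beidougen,2.03,0.89,6.33,0
23,BLETILLAE RHIZOMA,Baiji,1.78,0.92,4.57,1
24,SWERTIAE HERBA,Dangyao,3.92,0.53,5.75,0
25,MELIAE CORTEX,Kulianpi,1.47,0.84,6.78,1
26,NELUMBINIS PLUMULA,Lianzixin,3.47,1.17,6.86,1
27,FRAXINI CORTEX,Qinpi,1.40,0.63,6.18,1
28,COPTIDIS RHIZOMA,Huanglian,4.45,0.77,7.70,0
29,SOPHORAE FLAVESCENTIS RADIX,Kushen,4.78,0.63,6.91,0
30,GENTIANAE RADIX ET RHIZOMA,Longdan,4.55,0.68,5.79,0
31,PHELLODENDRI CHINENSIS CORTEX,Huangbo,4.66,0.69,6.56,0
32,BRUCEAE FRUCTUS,Yadanzi,1.10,0.50,8.56,1
33,ANDROGRAPHIS HERBA,Chuanxinlian,4.04,0.52,6.70,0
34,PICRORHIZAE RHIZOMA,Huhuanglian,4.67,0.54,4.65,0
35,PICRASMAE RAMULUS ET FOLIUM,Kumu,4.08,0.75,7.89,0
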