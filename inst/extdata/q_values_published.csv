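year,factor,q,stars
1980,MT,0.30,*
1980,MP,0.66,**
1980,MD,0.25,*
1980,MS,0.54,**
1980,PD,0.23,*
1980,EPR,0.15,
1980,PI,0.08,
1980,FR,0.09,
1980,GY,0.23,*
1980,PG,0.08,
1980,PC,0.11,
1980,IR,0.09,
1980,IS,0.1,
1980,IOR,0.087,
1980,GRGR,,
1990,MT,0.29,**
1990,MP,0.72,**
1990,MD,0.25,*
1990,MS,0.51,**
1990,PD,0.23,*
1990,EPR,0.06,
1990,PI,0.2,
1990,FR,0.06,
1990,GY,0.16,
1990,PG,0.048,
1990,PC,0.16,
1990,IR,0.12,
1990,IS,0.16,
1990,IOR,0.18,
1990,GRGR,,
2000,MT,0.32,**
2000,MP,0.72,**
2000,MD,0.26,*
2000,MS,0.56,**
2000,PD,0.07,
2000,EPR,0.115,
2000,PI,0.034,
2000,FR,0.048,
2000,GY,0.28,*
2000,PG,0.16,
2000,PC,0.06,
2000,IR,0.11,
2000,IS,0.022,
2000,IOR,0.068,
2000,GRGR,,
2010,MT,0.30,*
2010,MP,0.79,**
2010,MD,0.261,*
2010,MS,0.6,**
2010,PD,0.06,
2010,EPR,0.07,
2010,PI,0.13,
2010,FR,0.03,
2010,GY,0.09,
2010,PG,0.11,
2010,PC,0.06,
2010,IR,0.18,
2010,IS,0.04,
2010,IOR,0.06,
2010,GRGR,0.245,*
2019,MT,0.33,**
2019,MP,0.72,**
2019,MD,0.16,
2019,MS,0.57,**
2019,PD,0.17,
2019,EPR,0.093,
2019,PI,0.003,
2019,FR,0.175,
2019,GY,0.234,*
2019,PG,0.16,
2019,PC,0.027,
2019,IR,0.049,
2019,IS,0.02,
2019,IOR,0.23,
2019,GRGR,0.31,**
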