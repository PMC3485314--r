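species,age_days,age_unit,type,rate,reference
Thunnus thynnus,3,dph,instantaneous,0.2,Scott et al. (1993)
Thunnus thynnus,10,dph,instantaneous,0.2,Scott et al. (1993)
Thunnus albacares,3,dpef,instantaneous,0.16,Lang et al. (1994)
Thunnus albacares,14,dpef,instantaneous,0.41,Lang et al. (1994)
Thunnus maccoyii,11,dph,instantaneous,0.68,Davis et al. (1991)
Thunnus maccoyii,12,dph,instantaneous,0.97,Davis et al. (1991)
Thunnus orientalis,5,dph,instantaneous,1.66,Satoh et al. (2008)
Thunnus orientalis,6,dph,instantaneous,2.41,Satoh et al. (2008)
Thunnus orientalis,7,dph,instantaneous,2.75,Satoh et al. (2008)
Thunnus orientalis,8,dph,instantaneous,0.06,Satoh et al. (2008)
Thunnus orientalis,9,dph,instantaneous,1.74,Satoh et al. (2008)
Thunnus orientalis,11,dph,instantaneous,1.52,Satoh et al. (2008)
Thunnus orientalis,12,dph,instantaneous,1.52,Satoh et al. (2008)
Scomber scombrus,11.42,dph,cumulative,6.02,Ware and Lambert (1985)
Scomber scombrus,17.3,dph,cumulative,8.14,Ware and Lambert (1985)
Engraulis encrasicolus,100,dph,cumulative,5.99,Allain et al. (2007)
Engraulis encrasicolus,100,dph,cumulative,6.5,Allain et al. (2007)
Engraulis encrasicolus,180,dph,cumulative,9.94,Pertierra et al. (1997)
Engraulis mordax,180,dph,cumulative,9.56,Lo et al. (1995)
Sardinops sagax,180,dph,cumulative,12.25,Lo et al. (1995)
Sardinops caeruleus,180,dph,cumulative,7.88,Lo et al. (1995)
Sardinops caeruleus,180,dph,cumulative,8.465,Lo et al. (1995)
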