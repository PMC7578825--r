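individual_id,group,prey_taxon,count,mass
sj_mean,small_juvenile,detritus,NA,94.1
sj_mean,small_juvenile,Chaetophorales,NA,5.5
sj_mean,small_juvenile,Mytiloida,NA,0
sj_mean,small_juvenile,Coscinodiscales,NA,0.2
sj_mean,small_juvenile,Araphidiales,NA,0.2
sj_mean,small_juvenile,Ulvales,NA,0
lj_mean,large_juvenile,detritus,NA,84.5
lj_mean,large_juvenile,Chaetophorales,NA,1.4
lj_mean,large_juvenile,Mytiloida,NA,13.8
lj_mean,large_juvenile,Coscinodiscales,NA,0.02
lj_mean,large_juvenile,Araphidiales,NA,0.05
lj_mean,large_juvenile,Ulvales,NA,0.1
sa_mean,sub_adult,detritus,NA,96.8
sa_mean,sub_adult,Chaetophorales,NA,0
sa_mean,sub_adult,Mytiloida,NA,3.1
sa_mean,sub_adult,Coscinodiscales,NA,0.08
sa_mean,sub_adult,Araphidiales,NA,0.04
sa_mean,sub_adult,Ulvales,NA,0
ad_mean,adult,detritus,NA,92.7
ad_mean,adult,Chaetophorales,NA,0
ad_mean,adult,Mytiloida,NA,7.2
ad_mean,adult,Coscinodiscales,NA,0.05
ad_mean,adult,Araphidiales,NA,0.01
ad_mean,adult,Ulvales,NA,0
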