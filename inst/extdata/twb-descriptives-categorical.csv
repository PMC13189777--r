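factor,level,men_count,men_pct,women_count,women_pct
sample_size,,25375,36.5,44087,63.5
cooking,1,18111,71.4,9582,21.7
cooking,2,163,0.6,479,1.1
cooking,3,7101,28.0,34026,77.2
nut,1,24527,96.7,44046,99.9
nut,2,615,2.4,34,NA
nut,3,233,0.9,7,NA
supplement,1,11458,45.2,14688,33.3
supplement,2,5128,20.2,12454,28.2
supplement,3,8789,34.6,16945,38.4
alone,1,1680,6.6,4343,9.9
job,1,17181,67.7,25624,58.1
jobsame,1,2307,9.1,3741,8.5
medication,1,153,0.6,319,0.7
coffee,1,12002,47.3,20825,47.2
tea,1,7589,29.9,8330,18.9
drinking,1,3853,15.2,1091,2.5
smoking,1,4204,16.6,990,2.2
smk2nd,1,3189,12.6,3483,7.9
incense,1,5861,23.1,11597,26.3
vege,1,1905,7.5,4463,10.1
supper,1,9712,38.3,13562,30.8
spo_yesyes,1,8166,32.2,12703,28.8
spo_yesno,1,2860,11.3,4856,11.0
spo_noyes,1,3335,13.1,6043,13.7
spo_nono,1,11002,43.4,20456,46.4
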