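ID,Sex,MotherID,FatherID,isProband,CurAge,isAffBC,isAffOC,AgeBC,AgeOC,isDead
1,0,NA,NA,0,93,1,0,65,NA,1
2,1,NA,NA,0,80,0,0,NA,NA,1
3,0,1,2,0,72,1,1,40,NA,0
4,1,1,2,0,65,0,0,NA,NA,1
5,1,1,2,0,65,0,0,NA,NA,0
6,0,1,2,1,55,0,0,NA,NA,0
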