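pc	toxin	hotspots	traits
Carmustine.PC1	carmustine	V	mean.EXT,mean.TOF,q75.EXT,median.EXT,median.TOF,q75.TOF,median.norm.EXT,q90.TOF,q90.EXT
Carmustine.PC6	carmustine	IVL	q25.norm.EXT,q10.norm.EXT
Chlorothalonil.PC1	chlorothalonil	V	mean.EXT,q75.EXT,mean.TOF,median.EXT,median.TOF,q75.TOF
Chlorothalonil.PC2	chlorothalonil	IVL	cv.TOF,cv.EXT
Chlorothalonil.PC3	chlorothalonil	IVL,IVR	mean.norm.EXT,q75.norm.EXT,q90.norm.EXT,median.norm.EXT
Cisplatin.PC1	cisplatin	IVL,V	mean.EXT,mean.TOF,median.EXT,median.TOF,q75.TOF,q75.EXT,q90.EXT,q90.TOF
Cisplatin.PC3	cisplatin	IVL	var.TOF,var.EXT
Cisplatin.PC4	cisplatin	V	norm.n,n
Fluoxetine.PC1	fluoxetine	IVR	mean.norm.EXT,q75.norm.EXT,mean.EXT,q75.EXT,q90.norm.EXT,q90.EXT
Fluoxetine.PC5	fluoxetine	IVR	q90.norm.EXT,q75.norm.EXT,mean.norm.EXT,q75.EXT,mean.EXT,q90.EXT
Irinotecan.PC2	irinotecan	IVR	cv.TOF,cv.EXT
Paraquat.PC1	paraquat	V	median.EXT,mean.EXT,q25.EXT,q75.EXT,mean.TOF,q75.TOF,q10.EXT,q90.EXT,q90.TOF,median.TOF,q25.TOF,q10.TOF
Silver.PC1	silver	V	mean.EXT,median.EXT,q75.EXT,mean.TOF,q90.EXT,q90.TOF,median.TOF,q75.TOF
Silver.PC3	silver	IVL	q10.norm.EXT,q25.norm.EXT,mean.norm.EXT,median.norm.EXT,q75.norm.EXT,q90.norm.EXT
Silver.PC4	silver	IVL	n,norm.n
Silver.PC5	silver	IVL	n,norm.n
Tunicamycin.PC1	tunicamycin	IVL	median.EXT,q75.EXT,mean.TOF,q75.TOF,median.TOF,median.norm.EXT,q90.EXT,q90.TOF,mean.EXT,q75.norm.EXT,mean.norm.EXT,q25.norm.EXT,q90.norm.EXT,q10.norm.EXT
Tunicamycin.PC3	tunicamycin	IVL	norm.n,n
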