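class,generic,brands,match_mode
GLP-1RA,exenatide,BYETTA;BYDUREON,word
GLP-1RA,liraglutide,VICTOZA;SAXENDA,word
GLP-1RA,dulaglutide,TRULICITY,word
GLP-1RA,semaglutide,OZEMPIC;RYBELSUS;WEGOVY,word
GLP-1RA,tirzepatide,MOUNJARO,word
DPP-4 inhibitor,sitagliptin,JANUVIA,word
DPP-4 inhibitor,saxagliptin,ONGLYZA,word
DPP-4 inhibitor,linagliptin,TRADJENTA,word
DPP-4 inhibitor,alogliptin,NESINA,word
DPP-4 inhibitor,vildagliptin,GALVUS,word
sulfonylurea,glimepiride,AMARYL,word
sulfonylurea,glipizide,GLUCOTROL,word
sulfonylurea,glyburide,DIABETA;GLYNASE,word
sulfonylurea,gliclazide,DIAMICRON,word
metformin,metformin,GLUCOPHAGE;FORTAMET;GLUMETZA,word
SGLT2 inhibitor,empagliflozin,JARDIANCE,word
SGLT2 inhibitor,dapagliflozin,FARXIGA,word
SGLT2 inhibitor,canagliflozin,INVOKANA,word
thiazolidinedione,pioglitazone,ACTOS,word
thiazolidinedione,rosiglitazone,AVANDIA,word
insulin,insulin,LANTUS;BASAGLAR;NOVOLOG;HUMALOG;LEVEMIR,word
anti-obesity,orlistat,XENICAL;ALLI,word
anti-obesity,phentermine,ADIPEX-P;LOMAIRA,word
anti-obesity,naltrexone-bupropion,CONTRAVE,word
anti-obesity,phentermine-topiramate,QSYMIA,word
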