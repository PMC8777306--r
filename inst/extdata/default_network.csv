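trial_id,drug_code,drug_name,class_code,enrollment
TRIAL001,A10BA02,metformin,A10BA,6506
TRIAL002,A10BA02,metformin,A10BA,2308
TRIAL003,A10BA02,metformin,A10BA,1637
TRIAL004,A10BA02,metformin,A10BA,1148
TRIAL005,A10BA02,metformin,A10BA,1022
TRIAL006,A10BA02,metformin,A10BA,1020
TRIAL007,A10BA02,metformin,A10BA,988
TRIAL008,A10BA02,metformin,A10BA,334
TRIAL009,A10BA02,metformin,A10BA,300
TRIAL010,A10BA02,metformin,A10BA,300
TRIAL011,A10BA02,metformin,A10BA,300
TRIAL012,A10BB07,glipizide,A10BB,372
TRIAL013,A10BB09,gliclazide,A10BB,892
TRIAL014,A10BB09,gliclazide,A10BB,575
TRIAL015,A10BB12,glimepiride,A10BB,521
TRIAL016,A10BB12,glimepiride,A10BB,441
TRIAL017,A10BB12,glimepiride,A10BB,300
TRIAL018,A10BG02,rosiglitazone,A10BG,2055
TRIAL019,A10BG02,rosiglitazone,A10BG,830
TRIAL020,A10BG02,rosiglitazone,A10BG,764
TRIAL021,A10BG02,rosiglitazone,A10BG,682
TRIAL022,A10BG02,rosiglitazone,A10BG,657
TRIAL023,A10BG02,rosiglitazone,A10BG,564
TRIAL024,A10BG03,pioglitazone,A10BG,8395
TRIAL025,A10BG03,pioglitazone,A10BG,1154
TRIAL026,A10BG03,pioglitazone,A10BG,744
TRIAL027,A10BG03,pioglitazone,A10BG,636
TRIAL028,A10BG03,pioglitazone,A10BG,604
TRIAL029,A10BG03,pioglitazone,A10BG,300
TRIAL030,A10BG03,pioglitazone,A10BG,300
TRIAL031,A10BG03,pioglitazone,A10BG,300
TRIAL032,A10BH01,sitagliptin,A10BH,13614
TRIAL033,A10BH01,sitagliptin,A10BH,5559
TRIAL034,A10BH01,sitagliptin,A10BH,1711
TRIAL035,A10BH01,sitagliptin,A10BH,1710
TRIAL036,A10BH01,sitagliptin,A10BH,1626
TRIAL037,A10BH01,sitagliptin,A10BH,1290
TRIAL038,A10BH01,sitagliptin,A10BH,1146
TRIAL039,A10BH01,sitagliptin,A10BH,915
TRIAL040,A10BH01,sitagliptin,A10BH,909
TRIAL041,A10BH01,sitagliptin,A10BH,642
TRIAL042,A10BH01,sitagliptin,A10BH,587
TRIAL043,A10BH01,sitagliptin,A10BH,522
TRIAL044,A10BH01,sitagliptin,A10BH,466
TRIAL045,A10BH01,sitagliptin,A10BH,424
TRIAL046,A10BH01,sitagliptin,A10BH,300
TRIAL047,A10BH01,sitagliptin,A10BH,300
TRIAL048,A10BH02,vildagliptin,A10BH,1755
TRIAL049,A10BH02,vildagliptin,A10BH,1279
TRIAL050,A10BH02,vildagliptin,A10BH,1001
TRIAL051,A10BH02,vildagliptin,A10BH,901
TRIAL052,A10BH02,vildagliptin,A10BH,589
TRIAL053,A10BH02,vildagliptin,A10BH,377
TRIAL054,A10BH02,vildagliptin,A10BH,300
TRIAL055,A10BH02,vildagliptin,A10BH,300
TRIAL056,A10BH02,vildagliptin,A10BH,300
TRIAL057,A10BH03,saxagliptin,A10BH,7650
TRIAL058,A10BH03,saxagliptin,A10BH,1455
TRIAL059,A10BH03,saxagliptin,A10BH,711
TRIAL060,A10BH03,saxagliptin,A10BH,468
TRIAL061,A10BH03,saxagliptin,A10BH,351
TRIAL062,A10BH03,saxagliptin,A10BH,330
TRIAL063,A10BH03,saxagliptin,A10BH,301
TRIAL064,A10BH03,saxagliptin,A10BH,300
TRIAL065,A10BH04,alogliptin,A10BH,2945
TRIAL066,A10BH04,alogliptin,A10BH,1980
TRIAL067,A10BH04,alogliptin,A10BH,1533
TRIAL068,A10BH04,alogliptin,A10BH,1357
TRIAL069,A10BH04,alogliptin,A10BH,300
TRIAL070,A10BH04,alogliptin,A10BH,300
TRIAL071,A10BH05,linagliptin,A10BH,3422
TRIAL072,A10BH05,linagliptin,A10BH,1652
TRIAL073,A10BH05,linagliptin,A10BH,1184
TRIAL074,A10BH05,linagliptin,A10BH,826
TRIAL075,A10BH05,linagliptin,A10BH,520
TRIAL076,A10BH05,linagliptin,A10BH,387
TRIAL077,A10BH05,linagliptin,A10BH,300
TRIAL078,A10BH05,linagliptin,A10BH,300
TRIAL079,A10BH06,gemigliptin,A10BH,391
TRIAL080,A10BH06,gemigliptin,A10BH,300
TRIAL081,A10BJ01,exenatide,A10BJ,1382
TRIAL082,A10BJ01,exenatide,A10BJ,839
TRIAL083,A10BJ01,exenatide,A10BJ,572
TRIAL084,A10BJ01,exenatide,A10BJ,501
TRIAL085,A10BJ01,exenatide,A10BJ,300
TRIAL086,A10BJ01,exenatide,A10BJ,300
TRIAL087,A10BJ01,exenatide,A10BJ,300
TRIAL088,A10BJ01,exenatide,A10BJ,300
TRIAL089,A10BJ01,exenatide,A10BJ,300
TRIAL090,A10BJ02,liraglutide,A10BJ,9727
TRIAL091,A10BJ02,liraglutide,A10BJ,2378
TRIAL092,A10BJ02,liraglutide,A10BJ,2219
TRIAL093,A10BJ02,liraglutide,A10BJ,2071
TRIAL094,A10BJ02,liraglutide,A10BJ,1269
TRIAL095,A10BJ02,liraglutide,A10BJ,1061
TRIAL096,A10BJ02,liraglutide,A10BJ,939
TRIAL097,A10BJ02,liraglutide,A10BJ,918
TRIAL098,A10BJ02,liraglutide,A10BJ,730
TRIAL099,A10BJ02,liraglutide,A10BJ,695
TRIAL100,A10BJ02,liraglutide,A10BJ,427
TRIAL101,A10BJ02,liraglutide,A10BJ,421
TRIAL102,A10BJ02,liraglutide,A10BJ,404
TRIAL103,A10BJ02,liraglutide,A10BJ,370
TRIAL104,A10BJ03,lixisenatide,A10BJ,881
TRIAL105,A10BJ03,lixisenatide,A10BJ,803
TRIAL106,A10BJ03,lixisenatide,A10BJ,649
TRIAL107,A10BJ03,lixisenatide,A10BJ,300
TRIAL108,A10BJ04,albiglutide,A10BJ,2164
TRIAL109,A10BJ04,albiglutide,A10BJ,1944
TRIAL110,A10BJ04,albiglutide,A10BJ,680
TRIAL111,A10BJ04,albiglutide,A10BJ,396
TRIAL112,A10BJ05,dulaglutide,A10BJ,2445
TRIAL113,A10BJ05,dulaglutide,A10BJ,1652
TRIAL114,A10BJ05,dulaglutide,A10BJ,830
TRIAL115,A10BJ05,dulaglutide,A10BJ,640
TRIAL116,A10BJ05,dulaglutide,A10BJ,505
TRIAL117,A10BJ05,dulaglutide,A10BJ,478
TRIAL118,A10BJ05,dulaglutide,A10BJ,304
TRIAL119,A10BJ05,dulaglutide,A10BJ,300
TRIAL120,A10BJ06,semaglutide,A10BJ,10165
TRIAL121,A10BJ06,semaglutide,A10BJ,1623
TRIAL122,A10BJ06,semaglutide,A10BJ,847
TRIAL123,A10BJ06,semaglutide,A10BJ,582
TRIAL124,A10BJ06,semaglutide,A10BJ,573
TRIAL125,A10BJ06,semaglutide,A10BJ,312
TRIAL126,A10BJ06,semaglutide,A10BJ,300
TRIAL127,A10BJ07,taspoglutide,A10BJ,392
TRIAL128,A10BK01,dapagliflozin,A10BK,1638
TRIAL129,A10BK01,dapagliflozin,A10BK,992
TRIAL130,A10BK01,dapagliflozin,A10BK,771
TRIAL131,A10BK01,dapagliflozin,A10BK,757
TRIAL132,A10BK01,dapagliflozin,A10BK,634
TRIAL133,A10BK01,dapagliflozin,A10BK,628
TRIAL134,A10BK01,dapagliflozin,A10BK,626
TRIAL135,A10BK01,dapagliflozin,A10BK,557
TRIAL136,A10BK01,dapagliflozin,A10BK,370
TRIAL137,A10BK01,dapagliflozin,A10BK,354
TRIAL138,A10BK02,canagliflozin,A10BK,7650
TRIAL139,A10BK02,canagliflozin,A10BK,2080
TRIAL140,A10BK02,canagliflozin,A10BK,1331
TRIAL141,A10BK02,canagliflozin,A10BK,1270
TRIAL142,A10BK02,canagliflozin,A10BK,980
TRIAL143,A10BK02,canagliflozin,A10BK,917
TRIAL144,A10BK02,canagliflozin,A10BK,821
TRIAL145,A10BK02,canagliflozin,A10BK,758
TRIAL146,A10BK02,canagliflozin,A10BK,754
TRIAL147,A10BK03,empagliflozin,A10BK,10083
TRIAL148,A10BK03,empagliflozin,A10BK,3753
TRIAL149,A10BK03,empagliflozin,A10BK,2210
TRIAL150,A10BK03,empagliflozin,A10BK,920
TRIAL151,A10BK03,empagliflozin,A10BK,806
TRIAL152,A10BK03,empagliflozin,A10BK,640
TRIAL153,A10BK03,empagliflozin,A10BK,593
TRIAL154,A10BK03,empagliflozin,A10BK,300
TRIAL155,A10BK03,empagliflozin,A10BK,300
TRIAL156,A10BK03,empagliflozin,A10BK,300
TRIAL157,A10BK04,ertugliflozin,A10BK,1200
TRIAL158,A10BK04,ertugliflozin,A10BK,562
TRIAL159,A10BK04,ertugliflozin,A10BK,300
TRIAL160,A10BX02,repaglinide,A10BX,783
TRIAL161,A10BX02,repaglinide,A10BX,485
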