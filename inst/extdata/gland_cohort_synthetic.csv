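patient_id,site,truth,call_a,call_b
P01,right-upper,1,1,1
P01,right-lower,0,0,0
P01,left-upper,1,0,0
P01,left-lower,0,0,0
P02,right-upper,1,1,1
P02,right-lower,0,0,0
P02,left-upper,1,0,0
P02,left-lower,0,0,0
P03,right-upper,1,1,1
P03,right-lower,0,0,0
P03,left-upper,1,0,0
P03,left-lower,0,0,0
P04,right-upper,1,1,1
P04,right-lower,0,0,0
P04,left-upper,1,0,0
P04,left-lower,0,0,0
P05,right-upper,1,1,1
P05,right-lower,0,0,0
P05,left-upper,1,0,0
P05,left-lower,0,0,0
P06,right-upper,1,1,1
P06,right-lower,0,0,0
P06,left-upper,1,0,0
P06,left-lower,0,0,0
P07,right-upper,1,1,1
P07,right-lower,0,0,0
P07,left-upper,1,0,0
P07,left-lower,0,0,0
P08,right-upper,1,1,1
P08,right-lower,0,0,0
P08,left-upper,1,0,0
P08,left-lower,0,0,0
P09,right-upper,1,1,1
P09,right-lower,0,0,0
P09,left-upper,1,0,0
P09,left-lower,0,0,0
P10,right-upper,1,1,1
P10,right-lower,0,0,0
P10,left-upper,1,0,0
P10,left-lower,0,0,0
P11,right-upper,1,1,1
P11,right-lower,0,0,0
P11,left-upper,1,0,0
P11,left-lower,0,0,0
P12,right-upper,1,1,1
P12,right-lower,0,0,0
P12,left-upper,1,0,0
P12,left-lower,0,0,0
P13,right-upper,1,1,1
P13,right-lower,0,0,0
P13,left-upper,1,0,0
P13,left-lower,0,0,0
P14,right-upper,1,1,1
P14,right-lower,0,0,0
P14,left-upper,1,0,0
P14,left-lower,0,0,0
P15,right-upper,1,1,1
P15,right-lower,0,0,0
P15,left-upper,1,0,0
P15,left-lower,0,0,0
P16,right-upper,1,1,1
P16,right-lower,0,0,0
P16,left-upper,1,0,1
P16,left-lower,0,0,0
P17,right-upper,1,1,1
P17,right-lower,0,0,0
P17,left-upper,1,1,1
P17,left-lower,0,0,0
P18,right-upper,1,1,1
P18,right-lower,0,0,0
P18,left-upper,1,1,1
P18,left-lower,0,0,0
P19,right-upper,1,1,1
P19,right-lower,0,0,0
P19,left-upper,1,1,1
P19,left-lower,0,0,0
P20,right-upper,1,1,1
P20,right-lower,0,0,0
P20,left-upper,1,1,1
P20,left-lower,0,0,0
P21,right-upper,1,1,1
P21,right-lower,0,0,0
P21,left-upper,1,1,1
P21,left-lower,0,0,0
P22,right-upper,1,1,1
P22,right-lower,0,0,0
P22,left-upper,1,1,1
P22,left-lower,0,0,0
P23,right-upper,1,1,1
P23,right-lower,0,0,0
P23,left-upper,0,0,0
P23,left-lower,0,0,0
P24,right-upper,1,1,1
P24,right-lower,0,0,0
P24,left-upper,0,0,0
P24,left-lower,0,0,0
P25,right-upper,1,1,1
P25,right-lower,0,0,0
P25,left-upper,0,0,0
P25,left-lower,0,0,0
P26,right-upper,1,1,1
P26,right-lower,0,0,0
P26,left-upper,0,0,0
P26,left-lower,0,0,0
P27,right-upper,1,1,1
P27,right-lower,0,0,0
P27,left-upper,0,0,0
P27,left-lower,0,0,0
P28,right-upper,1,1,1
P28,right-lower,0,0,0
P28,left-upper,0,0,0
P28,left-lower,0,0,0
P29,right-upper,1,1,1
P29,right-lower,0,0,0
P29,left-upper,0,0,0
P29,left-lower,0,0,0
P30,right-upper,1,1,1
P30,right-lower,0,0,0
P30,left-upper,0,0,0
P30,left-lower,0,0,0
P31,right-upper,1,1,1
P31,right-lower,0,0,0
P31,left-upper,0,0,0
P31,left-lower,0,0,0
P32,right-upper,1,1,1
P32,right-lower,0,0,0
P32,left-upper,0,0,0
P32,left-lower,0,0,0
P33,right-upper,1,1,1
P33,right-lower,0,0,0
P33,left-upper,0,0,0
P33,left-lower,0,0,0
P34,right-upper,1,1,1
P34,right-lower,0,0,0
P34,left-upper,0,0,0
P34,left-lower,0,0,0
P35,right-upper,1,1,1
P35,right-lower,0,0,0
P35,left-upper,0,0,0
P35,left-lower,0,0,0
P36,right-upper,1,1,1
P36,right-lower,0,0,0
P36,left-upper,0,0,0
P36,left-lower,0,0,0
P37,right-upper,1,1,1
P37,right-lower,0,0,0
P37,left-upper,0,0,0
P37,left-lower,0,0,0
P38,right-upper,1,1,1
P38,right-lower,0,0,0
P38,left-upper,0,0,0
P38,left-lower,0,0,0
P39,right-upper,1,1,1
P39,right-lower,0,0,0
P39,left-upper,0,0,0
P39,left-lower,0,0,0
P40,right-upper,1,1,1
P40,right-lower,0,0,0
P40,left-upper,0,0,0
P40,left-lower,0,0,0
P41,right-upper,1,1,1
P41,right-lower,0,0,0
P41,left-upper,0,0,0
P41,left-lower,0,0,0
P42,right-upper,1,1,1
P42,right-lower,0,0,0
P42,left-upper,0,0,0
P42,left-lower,0,0,0
P43,right-upper,1,1,1
P43,right-lower,0,0,0
P43,left-upper,0,0,0
P43,left-lower,0,0,0
P44,right-upper,1,1,1
P44,right-lower,0,0,0
P44,left-upper,0,0,0
P44,left-lower,0,0,0
P45,right-upper,1,1,1
P45,right-lower,0,0,0
P45,left-upper,0,0,0
P45,left-lower,0,0,0
P46,right-upper,1,1,1
P46,right-lower,0,0,0
P46,left-upper,0,0,0
P46,left-lower,0,0,0
P47,right-upper,1,1,1
P47,right-lower,0,0,0
P47,left-upper,0,0,0
P47,left-lower,0,0,0
P48,right-upper,1,1,1
P48,right-lower,0,0,0
P48,left-upper,0,0,0
P48,left-lower,0,0,0
P49,right-upper,1,1,1
P49,right-lower,0,0,0
P49,left-upper,0,0,0
P49,left-lower,0,0,0
P50,right-upper,1,1,1
P50,right-lower,0,0,0
P50,left-upper,0,0,0
P50,left-lower,0,0,0
P51,right-upper,1,1,1
P51,right-lower,0,0,0
P51,left-upper,0,0,0
P51,left-lower,0,0,0
P52,right-upper,1,1,1
P52,right-lower,0,0,0
P52,left-upper,0,0,0
P52,left-lower,0,0,0
P53,right-upper,1,1,1
P53,right-lower,0,0,0
P53,left-upper,0,0,0
P53,left-lower,0,0,0
P54,right-upper,0,0,0
P54,right-lower,0,1,0
P54,left-upper,0,0,0
P54,left-lower,0,0,0
P55,right-upper,0,0,0
P55,right-lower,0,1,0
P55,left-upper,0,0,0
P55,left-lower,0,0,0
P56,right-upper,0,0,0
P56,right-lower,0,1,0
P56,left-upper,0,0,0
P56,left-lower,0,0,0
P57,right-upper,0,0,0
P57,right-lower,0,1,1
P57,left-upper,0,0,0
P57,left-lower,0,0,0
P58,right-upper,0,0,0
P58,right-lower,0,0,1
P58,left-upper,0,0,0
P58,left-lower,0,0,0
P59,right-upper,0,0,0
P59,right-lower,0,0,1
P59,left-upper,0,0,0
P59,left-lower,0,0,0
P60,right-upper,0,0,0
P60,right-lower,0,0,1
P60,left-upper,0,0,0
P60,left-lower,0,0,0
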