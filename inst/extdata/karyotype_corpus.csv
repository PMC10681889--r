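karyotype,expected_group,note
"57,XX,+X,+4,+6,+10,+14,+17,+18,+21,+21[12]/46,XX[8]",D-GR,classic HeH stemline plus normal clone
"46,XY[20]",not_heh,normal male karyotype
"47,XY,+21[20]",not_heh,modal 47 below window
"50,XY,+4,+6,+10,+21[15]",not_heh,modal 50 below window
"92,XXYY[10]",not_heh,near-tetraploid above window
"46,XX,inc[10]",not_heh,incomplete but not hyperdiploid
"46,XX,t(9;22)(q34;q11)[20]",not_heh,Ph-positive but outside modal window
"52,XY,+5,+8,+10,+17,inc[10]",D-PR,named +5 forces poor risk despite inc
"54,XY,t(9;22)(q34;q11),+4,+6,+10,+14,+17,+18,+21,+21[9]",excluded,Ph-positive exclusion
"55,XY,t(9;22)(q34;q11.2),+4,+6,+8,+10,+14,+17,+18,+21,+21[10]",excluded,sub-band breakpoint still matches
"56,XX,+5,+5,+8,+8,+10,+10,+14,+14,+18,+18[10]",excluded,masked doubled hypodiploid pattern
"56,XY,+4,+4,+6,+6,+10,+10,+14,+14,+21,+21[12]",excluded,masked doubled with five tetrasomies
"54,XY,+8,+8,+10,+10,+14,+14,+21,+21[10]",excluded,masked doubled at the four-tetrasomy threshold
"54,XY,+8,+8,+10,+10,+14,+14,+21,+21,inc[10]",P-PR,even pattern but uncertain evidence never excludes
"57,XX,+X,+4,+6,+10,+14,+17,+18,+21,+21,+mar[12]",P-GR,marker makes 5 and 20 uncertain
"57,XY,+X,+4,+6,+10,+14,+17,+18,+21,+21,+mar[3]/46,XY[17]",P-GR,marker in stemline of two-clone karyotype
"57,XY,+X,+4,+6,+10,+14,+17,+18,+21,+21,inc[12]",P-GR,incomplete karyotype with 17 and 18 seen
"52,XY,+4,+6,+10,+14,+18,inc[10]",P-GR,only 18 of the profile seen before inc
"55,XY,+?4,+6,+8,+10,+14,+17,+18,+21,+21[10]",P-GR,uncertain token triggers provisional handling
"54,XX,+2,+6,+10,+14,+17,+21,+21,+mar[8]",P-GR,17 seen and marker hides the rest
"56,XX,+X,+4,+6,+9,+10,+14,+17,+21,+21,+mar[15]",P-GR,17 seen with marker
"53,XX,+4,+6,+10,+14,+21,+21,+mar[10]",P-PR,no profile chromosome seen and marker present
"52,XY,+6,+10,+14,+21,+21,+mar[7]",P-PR,no profile chromosome seen and marker present
"55,XY,+4,+6,+10,+14,+17,+18,+21,+21,+21[10]/56,idem,+5[4]",D-GR,stemline classified before idem subclone
"51,XX,+X,+6,+14,+18,+21[20]",D-GR,minimal HeH at modal 51
"50-52,XX,+4,+6,+10,+14,+18[cp10]",D-GR,count range partially overlapping window; composite
"51-56,XY,+X,+6,+10,+17,+18,+21[cp12]",D-GR,range count with composite notation
"51,XX,-7,+4,+6,+10,+14,+18,+21[9]",D-GR,monosomy 7 does not disturb the profile
"55,XY,i(17)(q10),+4,+6,+8,+10,+14,+18,+21,+21,+X[10]",D-GR,isochromosome adds no whole-chromosome gain
"52,XX,+21c,+4,+6,+10,+14,+18[20]",D-GR,constitutional +21 retained with warning
"57,XX,+X,+4,+6,+10,+14,+17,+18,+21,+21,+99[12]",D-GR,nonsense token preserved as warning only
"55,XY,+5,+6,+8,+10,+14,+17,+18,+20,+21[20]",D-PR,5 and 20 gained
"54,XX,+X,+4,+6,+10,+14,+18,+20,+21[12]",D-PR,20 gained alongside 18
"53,XY,+6,+10,+14,+17,+20,+21,+mar[10]",D-PR,named +20 decides despite marker
"58,XX,+X,+4,+5,+6,+10,+14,+17,+18,+20,+21,+21,+mar[10]",D-PR,5 and 20 named so marker is irrelevant
"55,XY,+4,+5,+6,+10,+14,+17,+18,+21,+21[20]",D-PR,5 gained with 17 and 18
"53,XX,+5,+6,+10,+14,+20,+21,+21[11]",D-PR,5 and 20 without 17 or 18
"67,XX,+X,+1,+2,+3,+4,+5,+6,+7,+8,+9,+10,+11,+12,+13,+14,+16,+17,+18,+19,+21,+21[5]",D-PR,modal 67 upper boundary with +5
"65,XX,+X,+X,+2,+3,+4,+5,+6,+8,+9,+10,+11,+12,+13,+14,+16,+17,+18,+21,+21[4]",D-PR,double +X with +5
"54,XX,+4,+6,+10,+14,+21,+21,+mar,inc[8]",P-PR,marker and incomplete together
"XX,+4",parse_error,missing leading count
"abc",parse_error,not a karyotype
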