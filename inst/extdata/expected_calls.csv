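scenario,reference,species,feature,call,provenance,anchor
LOW,CONTROL,eP,shape,transient_peak,expected_experiment,eIF2a-P immunoblot time course under 0.1 uM TG: transient phosphorylation peak between 30 and 90 min
LOW,CONTROL,A,level,up,expected_experiment,ATF4 immunoblot: protein increases during tolerable stress
LOW,CONTROL,C,level,up,expected_experiment,CHOP immunoblot: protein increases during tolerable stress
LOW,CONTROL,G,level,up,expected_experiment,GADD34 immunoblot: protein increases during tolerable stress
LOW,CONTROL,mA,level,unchanged,expected_experiment,ATF4 qPCR: no significant change under TG
LOW,CONTROL,mA,level,up,expected_simulation,simulated ATF4 mRNA: about two-fold induction
LOW,CONTROL,mC,level,up,expected_experiment,CHOP qPCR: marked increase after 1 h of treatment
LOW,CONTROL,mG,level,up,expected_experiment,GADD34 qPCR: about two-fold increase upon ER stress
HIGH,CONTROL,eP,shape,sustained,expected_experiment,eIF2a-P immunoblot under 10 uM TG: phosphorylation remains high for the whole 2 h
HIGH,CONTROL,A,level,up,expected_experiment,ATF4 immunoblot: protein increases during excessive stress
HIGH,CONTROL,C,level,up,expected_experiment,CHOP immunoblot: protein increases during excessive stress
HIGH,CONTROL,G,level,up,expected_experiment,GADD34 immunoblot: protein increases during excessive stress
HIGH,CONTROL,mA,level,unchanged,expected_experiment,ATF4 qPCR: no significant change under TG
HIGH,CONTROL,mA,level,up,expected_simulation,simulated ATF4 mRNA: about two-fold induction
HIGH,CONTROL,mC,level,up,expected_experiment,CHOP qPCR: marked increase after 1 h of treatment
HIGH,CONTROL,mG,level,up,expected_experiment,GADD34 qPCR: about two-fold increase upon ER stress
HIGH,LOW,A,t50,down,expected_experiment,ATF4 immunoblot: rise starts earlier at the high stress level
HIGH,LOW,C,t50,down,expected_experiment,CHOP immunoblot: rise starts earlier at the high stress level
GB_HIGH,HIGH,A,level,down,expected_experiment,ATF4 immunoblot: remarkable decrease with guanabenz pretreatment
GB_HIGH,HIGH,mC,level,down,expected_experiment,CHOP qPCR: reduced increase in guanabenz-pretreated samples
GB_HIGH,HIGH,C,level,down,expected_experiment,CHOP immunoblot: significant decrease with guanabenz pretreatment
GB_HIGH,HIGH,G,level,down,expected_experiment,GADD34 immunoblot: slight reduction with guanabenz pretreatment
GB_HIGH,HIGH,mA,level,unchanged,expected_experiment,ATF4 qPCR: expression not changed by guanabenz pretreatment
GB_HIGH,HIGH,mG,level,unchanged,expected_experiment,GADD34 qPCR: expression not changed by guanabenz pretreatment
GB_HIGH,HIGH,eP,level,unchanged,expected_experiment,eIF2a-P immunoblot: phosphorylation maintained (not reduced) under guanabenz
SI_CHOP_HIGH,HIGH,mC,level,down,expected_experiment,CHOP qPCR: direct silencing by siRNA
SI_CHOP_HIGH,HIGH,C,level,down,expected_experiment,CHOP immunoblot: protein strongly reduced by silencing
SI_CHOP_HIGH,HIGH,G,level,down,expected_experiment,GADD34 immunoblot: significantly milder activation when CHOP is silenced
SI_CHOP_HIGH,HIGH,mG,level,unchanged,expected_experiment,GADD34 qPCR: not affected at the mRNA level by CHOP silencing
SI_CHOP_HIGH,HIGH,mA,level,unchanged,expected_experiment,ATF4 qPCR: no change when CHOP silencing is combined with stress
SI_CHOP_HIGH,HIGH,A,level,unchanged,expected_experiment,ATF4 immunoblot: protein unaffected by CHOP silencing
SI_CHOP_HIGH,HIGH,eP,level,unchanged,expected_experiment,eIF2a-P immunoblot: similar characteristic with and without CHOP silencing
OE_CHOP_HIGH,HIGH,C,level,up,expected_experiment,CHOP overexpression: significant increase of CHOP activity under excessive stress
OE_GADD34_HIGH,HIGH,C,level,up,expected_experiment,GADD34 overexpression: significant increase of CHOP activity under excessive stress
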