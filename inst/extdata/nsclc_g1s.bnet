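# g1sbn Boolean network model
# node DNA_Damage input DNA-Damage
# node ATM internal ATM
# node Chk2 internal Chk2
# node p53 internal p53
# node Mdm2 internal Mdm2
# node Wip1 internal Wip1
# node p53INP1 internal p53-INP1
# node HIPK2 internal HIPK2
# node p53A internal p53-A
# node p53K internal p53-K
# node p21 internal p21
# node Bax internal Bax
# node Casp3 internal Caspase3
# node miR34a internal miR-34a
# node ANRIL internal ANRIL
# node UFC1 internal UFC1
# node EZH2 internal EZH2
# node PTEN internal PTEN
# node KLF2 internal KLF2
# node AKT internal AKT
# node Myc internal Myc
# node HDAC1 internal HDAC1
# node Sirt1 internal Sirt-1
# node E2F1 internal E2F1
# node RB internal RB
# node Cdc25A internal Cdc25A
# node BCL2 internal BCL2
# node CDK46_CycD internal CDK46/CycD
# node CDK2_CycE internal CDK2/CycE
# node Proliferation output Proliferation
# node Senescence output Senescence
# node Apoptosis output Apoptosis
# edge DNA_Damage ATM +
# edge Wip1 ATM -
# edge Sirt1 ATM -
# edge ATM Chk2 +
# edge ATM p53 +
# edge Mdm2 p53 -
# edge HDAC1 p53 -
# edge ATM Mdm2 -
# edge p53 Mdm2 +
# edge AKT Mdm2 +
# edge p53 Wip1 +
# edge p53A Wip1 +
# edge p53K Wip1 -
# edge p53A p53INP1 +
# edge Myc p53INP1 +
# edge HDAC1 p53INP1 +
# edge E2F1 p53INP1 +
# edge Wip1 HIPK2 -
# edge p53INP1 HIPK2 +
# edge BCL2 HIPK2 -
# edge p53 p53A +
# edge HIPK2 p53A -
# edge p53K p53A -
# edge p53 p53K +
# edge Mdm2 p53K -
# edge Wip1 p53K -
# edge p53A p53K -
# edge HDAC1 p53K +
# edge Cdc25A p53K +
# edge BCL2 p53K -
# edge p53A p21 +
# edge Casp3 p21 -
# edge KLF2 p21 +
# edge Myc p21 -
# edge HDAC1 p21 -
# edge p53K Bax +
# edge BCL2 Bax -
# edge p21 Casp3 -
# edge Bax Casp3 +
# edge ATM miR34a +
# edge p53 miR34a +
# edge ANRIL miR34a -
# edge UFC1 miR34a -
# edge EZH2 miR34a -
# edge Myc ANRIL +
# edge E2F1 ANRIL +
# edge E2F1 UFC1 +
# edge ANRIL EZH2 +
# edge UFC1 EZH2 +
# edge EZH2 PTEN -
# edge EZH2 KLF2 -
# edge PTEN AKT -
# edge p53 Myc -
# edge p21 Myc -
# edge miR34a Myc -
# edge AKT Myc +
# edge E2F1 Myc +
# edge miR34a HDAC1 -
# edge miR34a Sirt1 -
# edge E2F1 Sirt1 +
# edge p53 E2F1 -
# edge miR34a E2F1 -
# edge Myc E2F1 +
# edge Sirt1 E2F1 -
# edge RB E2F1 -
# edge CDK46_CycD RB -
# edge CDK2_CycE RB -
# edge Chk2 Cdc25A -
# edge miR34a Cdc25A -
# edge E2F1 Cdc25A +
# edge p53 BCL2 -
# edge miR34a BCL2 -
# edge AKT BCL2 +
# edge Myc BCL2 +
# edge p21 CDK46_CycD -
# edge miR34a CDK46_CycD -
# edge p21 CDK2_CycE -
# edge miR34a CDK2_CycE -
# edge E2F1 CDK2_CycE +
# edge Cdc25A CDK2_CycE +
# edge p21 Proliferation -
# edge Casp3 Proliferation -
# edge Cdc25A Proliferation +
# edge CDK46_CycD Proliferation +
# edge CDK2_CycE Proliferation +
# edge p21 Senescence +
# edge Casp3 Senescence -
# edge Casp3 Apoptosis +
targets, factors
DNA_Damage, DNA_Damage
ATM, DNA_Damage & !(Wip1 & Sirt1)
Chk2, ATM
p53, ATM | (!Mdm2 & !HDAC1)
Mdm2, (p53 | AKT) & !ATM
Wip1, p53A & (p53 | !p53K)
p53INP1, p53A & (HDAC1 | E2F1 | Myc)
HIPK2, p53INP1 & !(Wip1 & BCL2)
p53A, p53 & !(p53K | HIPK2)
p53K, p53 & !(p53A | Wip1 | Mdm2 | (BCL2 & !(HDAC1 & Cdc25A)))
p21, p53A & !(Casp3 | ((HDAC1 | Myc) & !KLF2))
Bax, p53K & !BCL2
Casp3, Bax & !p21
miR34a, (ATM | p53) & !(ANRIL | UFC1 | EZH2)
ANRIL, E2F1 | Myc
UFC1, E2F1
EZH2, ANRIL | UFC1
PTEN, !EZH2
KLF2, !EZH2
AKT, !PTEN
Myc, (E2F1 | AKT) & !(miR34a | p53 | p21)
HDAC1, !miR34a
Sirt1, E2F1 & !miR34a
E2F1, (Myc | (!RB & !p53 & !Sirt1)) & !miR34a
RB, !(CDK46_CycD | CDK2_CycE)
Cdc25A, E2F1 & !(miR34a | Chk2)
BCL2, (Myc | AKT) & !(miR34a | p53)
CDK46_CycD, !(miR34a | p21)
CDK2_CycE, (E2F1 | Cdc25A) & !(miR34a | p21)
Proliferation, CDK46_CycD & CDK2_CycE & Cdc25A & !(p21 | Casp3)
Senescence, p21 & !Casp3
Apoptosis, Casp3
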