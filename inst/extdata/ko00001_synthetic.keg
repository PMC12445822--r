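+D	KO
#<h2>Synthetic KO (KEGG Orthology) fixture</h2>
!
A09100 Metabolism
B  09101 Carbohydrate metabolism
C    00010 Glycolysis / Gluconeogenesis [PATH:ko00010]
D      K00844  HK; hexokinase [EC:2.7.1.1]
D      K01810  GPI; glucose-6-phosphate isomerase [EC:5.3.1.9]
D      K00850  PFK; 6-phosphofructokinase 1 [EC:2.7.1.11]
D      K01623  ALDO; fructose-bisphosphate aldolase, class I [EC:4.1.2.13]
D      K00134  GAPDH; glyceraldehyde 3-phosphate dehydrogenase [EC:1.2.1.12]
D      K01803  TPI; triosephosphate isomerase [EC:5.3.1.1]
D      K00927  PGK; phosphoglycerate kinase [EC:2.7.2.3]
D      K01689  ENO; enolase [EC:4.2.1.11]
D      K00873  PK; pyruvate kinase [EC:2.7.1.40]
C    00020 Citrate cycle (TCA cycle) [PATH:ko00020]
D      K01647  CS; citrate synthase [EC:2.3.3.1]
D      K01681  ACO; aconitate hydratase [EC:4.2.1.3]
D      K00031  IDH1; isocitrate dehydrogenase [EC:1.1.1.42]
D      K00164  OGDH; 2-oxoglutarate dehydrogenase E1 [EC:1.2.4.2]
D      K01899  LSC1; succinyl-CoA synthetase alpha subunit [EC:6.2.1.4]
D      K00234  SDHA; succinate dehydrogenase flavoprotein [EC:1.3.5.1]
D      K01679  FH; fumarate hydratase, class II [EC:4.2.1.2]
D      K00024  MDH1; malate dehydrogenase [EC:1.1.1.37]
D      K01623  ALDO; fructose-bisphosphate aldolase, class I [EC:4.1.2.13]
B  09102 Energy metabolism
C    00190 Oxidative phosphorylation [PATH:ko00190]
D      K02132  ATPeF1A; F-type H+-transporting ATPase subunit alpha
D      K02133  ATPeF1B; F-type H+-transporting ATPase subunit beta
A09120 Genetic Information Processing
B  09123 Folding, sorting and degradation
C    03018 RNA degradation [PATH:ko03018]
D      K03283  HSPA1; heat shock 70kDa protein 1/2/6/8
C    04141 Protein processing in endoplasmic reticulum [PATH:ko04141]
D      K03283  HSPA1; heat shock 70kDa protein 1/2/6/8
D      K09490  HSPA5; endoplasmic reticulum chaperone BiP
A09150 Organismal Systems
B  09149 Aging
C    04213 Longevity regulating pathway - multiple species [PATH:ko04213]
D      K04565  SOD1; superoxide dismutase, Cu-Zn family [EC:1.15.1.1]
D      K04564  SOD2; superoxide dismutase, Fe-Mn family [EC:1.15.1.1]
D      K03283  HSPA1; heat shock 70kDa protein 1/2/6/8
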