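label,category,oral_drugs,iv_drug,iv_days
R-E-CLAM,macrolide_susceptible,R;E;CLAM,,0
RBT-E-CLAM,macrolide_susceptible,RBT;E;CLAM,,0
R-E-AZM,macrolide_susceptible,R;E;AZM,,0
RBT-E-AZM,macrolide_susceptible,RBT;E;AZM,,0
R-E-CLO-AMK,macrolide_resistant,R;E;CLO,AMK,60
R-E-MOX-AMK,macrolide_resistant,R;E;MOX,AMK,60
R-E-CLAM-AMX,severe,R;E;CLAM,AMK,60
RBT-E-CLAM-AMX,severe,RBT;E;CLAM,AMK,60
R-E-ATZ-AMX,severe,R;E;AZM,AMK,60
RBT-E-ATM-AMX,severe,RBT;E;AZM,AMK,60
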