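# Budding-yeast cell-cycle network, 11 nodes.
# Transcribed from Li, Long, Lu, Ouyang & Tang (2004) PNAS 101:4781-4786
# ("The yeast cell-cycle network is robustly designed"), the model also used
# by Han & Wang for landscape analysis. Activating edges +1, inhibiting
# edges -1. The five self-degrading nodes (Cln3, Cln12, Swi5, Cdc20, Mcm1)
# carry a -0.1 self-loop, which under the hold-at-zero threshold rule is
# exactly equivalent to the original "decay when unregulated" convention
# because all other net inputs are integers.
# Initial state: stationary G1 (Cdh1 and Sic1 on). The excited "start
# signal" state additionally turns Cln3 on.
node initial_state basal_value
Cln3 0 0
MBF 0 0
SBF 0 0
Cln12 0 0
Cdh1 1 0
Swi5 0 0
Cdc20 0 0
Clb56 0 0
Sic1 1 0
Clb12 0 0
Mcm1 0 0
source target weight type
Cln3 MBF 1 activation
Cln3 SBF 1 activation
MBF Clb56 1 activation
SBF Cln12 1 activation
Clb56 Mcm1 1 activation
Clb56 Clb12 1 activation
Clb12 Mcm1 1 activation
Clb12 Cdc20 1 activation
Mcm1 Clb12 1 activation
Mcm1 Cdc20 1 activation
Mcm1 Swi5 1 activation
Cdc20 Swi5 1 activation
Cdc20 Cdh1 1 activation
Cdc20 Sic1 1 activation
Swi5 Sic1 1 activation
Cln12 Sic1 -1 inhibition
Cln12 Cdh1 -1 inhibition
Clb56 Sic1 -1 inhibition
Clb56 Cdh1 -1 inhibition
Clb12 Sic1 -1 inhibition
Clb12 Cdh1 -1 inhibition
Clb12 Swi5 -1 inhibition
Clb12 SBF -1 inhibition
Clb12 MBF -1 inhibition
Sic1 Clb56 -1 inhibition
Sic1 Clb12 -1 inhibition
Cdh1 Clb12 -1 inhibition
Cdc20 Clb56 -1 inhibition
Cdc20 Clb12 -1 inhibition
Cln3 Cln3 -0.1 inhibition
Cln12 Cln12 -0.1 inhibition
Swi5 Swi5 -0.1 inhibition
Cdc20 Cdc20 -0.1 inhibition
Mcm1 Mcm1 -0.1 inhibition
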