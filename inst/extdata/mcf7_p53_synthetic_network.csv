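# SYNTHETIC 16-node p53-signalling network for the MCF-7 treatment case
# study. The published weighted network (Choi et al. 2012, Sci. Signal.
# 5:ra83) is only available as journal supplementary data, so this fixture
# is a stand-in built from the same circuitry: ATM -> p53 activation with
# the Wip1 and MDM2 negative feedbacks, the p53 -> PTEN -> AKT -> MDM2
# positive feedback, a BCL2-gated BAX/caspase death switch with an
# absorbing committed state, and a p21/14-3-3sigma/Rb arrest arm.
# Treatments are encoded exactly as in the case study: Etoposide (E) sets
# the basal value of ATM to 1, WIP1 knock-down (W) sets the basal value of
# WIP1 to -1000, and Nutlin (N) deletes the MDM2 -> P53 interaction.
# Designed behavior (exhaustive DA over 2^16 states): untreated control
# converges to a single proliferation attractor; apoptotic basin share is
# strictly ordered E+N+W > N+W > E+N > N > E+W > E, with W alone inert.
node,initial_state,basal_value
ATM,0,0
P53,0,1
MDM2,1,1
WIP1,0,0
PTEN,0,0
AKT,1,1
CYCG,0,0
P21,0,0
SFN,0,0
CYCE,1,0
E2F1,1,1
RB,0,1
BAX,0,0
BCL2,1,-0.5
AIP1,0,-1
CASP,0,-1.5
source,target,weight,type
WIP1,ATM,-1,inhibition
ATM,ATM,-0.1,inhibition
MDM2,P53,-2.5,inhibition
WIP1,P53,-1,inhibition
ATM,P53,1,activation
P53,MDM2,1,activation
AKT,MDM2,1,activation
CYCG,MDM2,1,activation
ATM,MDM2,-1,inhibition
P53,WIP1,1,activation
WIP1,WIP1,-0.1,inhibition
P53,PTEN,1,activation
PTEN,PTEN,-0.1,inhibition
PTEN,AKT,-2,inhibition
P53,CYCG,1,activation
CYCG,CYCG,-0.1,inhibition
P53,P21,2,activation
AKT,P21,-1,inhibition
P21,P21,-0.1,inhibition
P53,SFN,1,activation
SFN,SFN,-0.1,inhibition
E2F1,CYCE,1,activation
P21,CYCE,-2,inhibition
SFN,CYCE,-1,inhibition
RB,E2F1,-2,inhibition
CYCE,RB,-2,inhibition
AKT,RB,-2,inhibition
P53,BAX,2,activation
BCL2,BAX,-1,inhibition
BAX,BAX,-0.1,inhibition
AKT,BCL2,1,activation
BCL2,BCL2,0.6,activation
CASP,BCL2,-2,inhibition
P53,AIP1,1,activation
ATM,AIP1,1,activation
WIP1,AIP1,-1,inhibition
BAX,CASP,1,activation
AIP1,CASP,1,activation
BCL2,CASP,-2,inhibition
CASP,CASP,1.4,activation
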