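# swdnet accepted screening candidates
# Regenerate each matrix with:
#   apply_collaterals(sample_matrix(network_layout(kind), tau_steps = tau_steps, seed = seed))
# focal: the intracortical excitability ramp elicits a spontaneously
#        terminating 4-12 Hz discharge while the protocol-free twin settles
#        (screened over 7000 candidates; listed candidates are those accepted
#        by classify_focal() at the reference initial-state seed 1)
# surrounding: sustained irregular activity without a dominant 3-15 Hz
#        spectral peak (screened over 200 candidates; accepted by
#        classify_surrounding() at the reference seed 1)
kind	seed	tau_steps
focal	2067	11
focal	2211	10
focal	4060	9
focal	5561	10
focal	5777	11
focal	6359	13
surrounding	1106	10
surrounding	1126	10
surrounding	1137	11
surrounding	1138	12
surrounding	1179	13
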