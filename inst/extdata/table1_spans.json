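{"amplicons":{"BRAF_600":{"primer_fwd":[0,20],"primer_rev":[83,103],"ipc_identifier":[24,32]},"EGFR_790":{"primer_fwd":[0,20],"primer_rev":[81,101],"ipc_identifier":[24,32]},"EGFR_858":{"primer_fwd":[0,20],"primer_rev":[82,102],"ipc_identifier":[24,32]},"EGFR_ex19":{"primer_fwd":[0,20],"primer_rev":[107,127],"ipc_identifier":[24,32]},"KRAS_12_13":{"primer_fwd":[0,20],"primer_rev":[85,105],"ipc_identifier":[24,32]},"PIK3CA_1047":{"primer_fwd":[0,20],"primer_rev":[81,101],"ipc_identifier":[24,32]},"PIK3CA_542_546":{"primer_fwd":[0,20],"primer_rev":[93,113],"ipc_identifier":[24,32]}}}
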