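name: pollack
channels:
  - name: SWS
    lambda_max_nm: 436
    relative_abundance: 0.70
  - name: LWS
    lambda_max_nm: 521
    relative_abundance: 1.00
ocular_cutoff_nm: 410
nu: 0.05
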