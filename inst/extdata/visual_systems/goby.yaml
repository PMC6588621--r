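name: goby
channels:
  - name: SWS
    lambda_max_nm: 456
    relative_abundance: 0.72
  - name: MWS
    lambda_max_nm: 531
    relative_abundance: 1.00
  - name: LWS
    lambda_max_nm: 553
    relative_abundance: 0.60
ocular_cutoff_nm: 410
nu: 0.05
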