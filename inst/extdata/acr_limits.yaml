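# Absolute image-quality limits per ACR CT Accreditation Program
# documentation (plain configuration; per-plug accepted HU ranges live in
# the phantom geometry configuration). The uniformity centre limit is
# given as +/-7 HU in some ACR material and +/-5 HU in others; both are
# listed here and +/-7 is applied by default.
uniformity:
  lo: 0.0
  hi: 5.0
  units: HU
uniformity_center:
  lo: -7.0
  hi: 7.0
  units: HU
uniformity_center_strict:
  lo: -5.0
  hi: 5.0
  units: HU
lowcontrast_cnr:
  lo: 1.0
  hi: .inf
  units: ""
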