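{
  "aberration_class": "rings",
  "c": 0.0,
  "alpha": 0.001,
  "beta": 0.051,
  "se_c": null,
  "se_alpha": null,
  "se_beta": null,
  "dose_unit": "Gy",
  "source": "CABAS regression of the G2-PCC ring dose-response series; fit protocol and dose range not recorded, reference only"
}
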