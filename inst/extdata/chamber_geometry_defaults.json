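{
  "provenance": "Cavity radii from manufacturer data sheets (PTW, IBA, Standard Imaging). NOT part of the published calibration-study data; override with your own chamber certificate values if they differ.",
  "cavity_radius_cm": {
    "PTW 30013": 0.305,
    "IBA CC13": 0.3,
    "Exradin A1Sl": 0.2
  }
}
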