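{
  "descriptors": ["nS", "GATS5s", "VR1_Dze", "ETA_dBetaP", "L3i"],
  "coefficients": [-0.124851343, -5.137570104, 0.000256939, 12.790319005, -0.173566533],
  "intercept": 6.319854761,
  "metadata": {
    "endpoint": "pIC50 against HCT116 colorectal cancer cell line",
    "chemistry": "imidazol-5-one derivatives",
    "training": "25-compound training set, genetic function algorithm selection",
    "source": "published five-descriptor MLR model, bundled as a fixture"
  }
}
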