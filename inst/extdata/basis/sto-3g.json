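{
  "name": "sto-3g",
  "synthetic": false,
  "note": "Minimal STO-3G from published 3-Gaussian Slater fits, standard zetas.",
  "elements": {
    "H": [
      {
        "l": 0,
        "exponents": [3.425250913958, 0.6239137294656, 0.1688561568],
        "coefficients": [0.154328967, 0.535328142, 0.444634542]
      }
    ],
    "He": [
      {
        "l": 0,
        "exponents": [6.362421393962, 1.158922998652, 0.3136511898],
        "coefficients": [0.154328967, 0.535328142, 0.444634542]
      }
    ],
    "C": [
      {
        "l": 0,
        "exponents": [71.616837348958, 13.045096317128, 3.5305279002],
        "coefficients": [0.154328967, 0.535328142, 0.444634542]
      },
      {
        "l": 0,
        "exponents": [2.9412501552, 0.6834821104, 0.22229003424],
        "coefficients": [-0.09996723, 0.39951283, 0.70011547]
      },
      {
        "l": 1,
        "exponents": [2.9412501552, 0.6834821104, 0.22229003424],
        "coefficients": [0.15591627, 0.60768372, 0.39195739]
      }
    ],
    "N": [
      {
        "l": 0,
        "exponents": [99.106168955518, 18.052312382168, 4.8856820202],
        "coefficients": [0.154328967, 0.535328142, 0.444634542]
      },
      {
        "l": 0,
        "exponents": [3.7804569075, 0.8784953775, 0.2857145265],
        "coefficients": [-0.09996723, 0.39951283, 0.70011547]
      },
      {
        "l": 1,
        "exponents": [3.7804569075, 0.8784953775, 0.2857145265],
        "coefficients": [0.15591627, 0.60768372, 0.39195739]
      }
    ],
    "O": [
      {
        "l": 0,
        "exponents": [130.70932136255, 23.808866040994, 6.4436370408],
        "coefficients": [0.154328967, 0.535328142, 0.444634542]
      },
      {
        "l": 0,
        "exponents": [5.0331526875, 1.1695944375, 0.3803891625],
        "coefficients": [-0.09996723, 0.39951283, 0.70011547]
      },
      {
        "l": 1,
        "exponents": [5.0331526875, 1.1695944375, 0.3803891625],
        "coefficients": [0.15591627, 0.60768372, 0.39195739]
      }
    ]
  }
}
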