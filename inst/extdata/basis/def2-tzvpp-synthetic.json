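{
  "name": "def2-tzvpp",
  "synthetic": true,
  "note": "SYNTHETIC stand-in: authentic def2-TZVPP shell composition (H 3s2p1d; C,N,O 5s3p2d1f) with even-tempered exponents and hydrogenic-eigenvector contractions. AO counts match def2-TZVPP exactly; energies are not those of the genuine set.",
  "elements": {
    "H": [
      {
        "l": 0,
        "exponents": [33.8272, 7.946188158451, 1.866601617914],
        "coefficients": [0.03101365236329, -0.08075315389571, 1.04604736822]
      },
      {
        "l": 0,
        "exponents": 0.4384745906494,
        "coefficients": 1
      },
      {
        "l": 0,
        "exponents": 0.103,
        "coefficients": 1
      },
      {
        "l": 1,
        "exponents": 1.41,
        "coefficients": 1
      },
      {
        "l": 1,
        "exponents": 0.39,
        "coefficients": 1
      },
      {
        "l": 2,
        "exponents": 1.06,
        "coefficients": 1
      }
    ],
    "C": [
      {
        "l": 0,
        "exponents": [9644.67, 3024.6592138949, 948.561574444672, 297.47783035508, 93.2918451863, 29.2572, 9.175333065078],
        "coefficients": [0.0004708350697466, 0.0004160126397167, 0.006664221098687, 0.01130102244694, 0.1017399042765, 0.1731465834186, 0.7970129366614]
      },
      {
        "l": 0,
        "exponents": 2.877470737292,
        "coefficients": 1
      },
      {
        "l": 0,
        "exponents": 0.9024018839696,
        "coefficients": 1
      },
      {
        "l": 0,
        "exponents": 0.28300171732,
        "coefficients": 1
      },
      {
        "l": 0,
        "exponents": 0.088752,
        "coefficients": 1
      },
      {
        "l": 1,
        "exponents": [36.98, 11.412965727124, 3.52233062976, 1.087080550488],
        "coefficients": [-0.001472423738319, 0.03940652549166, 0.01858357845755, 0.9771964234351]
      },
      {
        "l": 1,
        "exponents": 0.3355006237248,
        "coefficients": 1
      },
      {
        "l": 1,
        "exponents": 0.103544,
        "coefficients": 1
      },
      {
        "l": 2,
        "exponents": 1.360864,
        "coefficients": 1
      },
      {
        "l": 2,
        "exponents": 0.384592,
        "coefficients": 1
      },
      {
        "l": 3,
        "exponents": 0.828352,
        "coefficients": 1
      }
    ],
    "N": [
      {
        "l": 0,
        "exponents": [13346.670000000002, 4154.843577805192, 1293.410652696816, 402.641178947422, 125.342959443037, 39.0195, 12.146844043059],
        "coefficients": [0.0004518736591654, 0.0004645758841801, 0.006466797581534, 0.01214252395319, 0.1009552123134, 0.1850465695964, 0.7871979318221]
      },
      {
        "l": 0,
        "exponents": 3.781335491392,
        "coefficients": 1
      },
      {
        "l": 0,
        "exponents": 1.177136879981,
        "coefficients": 1
      },
      {
        "l": 0,
        "exponents": 0.3664449339039,
        "coefficients": 1
      },
      {
        "l": 0,
        "exponents": 0.114075,
        "coefficients": 1
      },
      {
        "l": 1,
        "exponents": [47.53125, 14.669349032379, 4.527333092097, 1.3972497949],
        "coefficients": [-0.001472423738319, 0.03940652549166, 0.01858357845755, 0.9771964234351]
      },
      {
        "l": 1,
        "exponents": 0.4312267177236,
        "coefficients": 1
      },
      {
        "l": 1,
        "exponents": 0.1330875,
        "coefficients": 1
      },
      {
        "l": 2,
        "exponents": 1.74915,
        "coefficients": 1
      },
      {
        "l": 2,
        "exponents": 0.494325,
        "coefficients": 1
      },
      {
        "l": 3,
        "exponents": 1.0647,
        "coefficients": 1
      }
    ],
    "O": [
      {
        "l": 0,
        "exponents": [17602.680000000004, 5484.91047865795, 1709.071741285516, 532.538539731172, 165.936449271401, 51.705, 16.111029473865],
        "coefficients": [0.0004509933148523, 0.0004378871402301, 0.006465396766674, 0.01166736900817, 0.1006008834831, 0.1794459717263, 0.7925587561473]
      },
      {
        "l": 0,
        "exponents": 5.020119344507,
        "coefficients": 1
      },
      {
        "l": 0,
        "exponents": 1.564245057957,
        "coefficients": 1
      },
      {
        "l": 0,
        "exponents": 0.4874112413324,
        "coefficients": 1
      },
      {
        "l": 0,
        "exponents": 0.151875,
        "coefficients": 1
      },
      {
        "l": 1,
        "exponents": [63.28125, 19.530198415889, 6.027514471727, 1.860243809777],
        "coefficients": [-0.001472423738319, 0.03940652549166, 0.01858357845755, 0.9771964234351]
      },
      {
        "l": 1,
        "exponents": 0.5741184111705,
        "coefficients": 1
      },
      {
        "l": 1,
        "exponents": 0.1771875,
        "coefficients": 1
      },
      {
        "l": 2,
        "exponents": 2.32875,
        "coefficients": 1
      },
      {
        "l": 2,
        "exponents": 0.658125,
        "coefficients": 1
      },
      {
        "l": 3,
        "exponents": 1.4175,
        "coefficients": 1
      }
    ]
  }
}
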