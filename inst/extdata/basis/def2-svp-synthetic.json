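{
  "name": "def2-svp",
  "synthetic": true,
  "note": "SYNTHETIC stand-in: authentic def2-SVP shell composition (H 2s1p; C,N,O 3s2p1d) with even-tempered exponents and hydrogenic-eigenvector contractions. AO counts match def2-SVP exactly; energies are not those of the genuine set.",
  "elements": {
    "H": [
      {
        "l": 0,
        "exponents": [13.0696, 2.751871439652, 0.5794206724285],
        "coefficients": [0.02946083935264, 0.05689180403376, 0.9527594830373]
      },
      {
        "l": 0,
        "exponents": 0.122,
        "coefficients": 1
      },
      {
        "l": 1,
        "exponents": 0.8,
        "coefficients": 1
      }
    ],
    "C": [
      {
        "l": 0,
        "exponents": [1221.6582, 271.724779514715, 60.437817879273, 13.442755704988, 2.98997692645],
        "coefficients": [0.004927858950627, 0.02540168416128, 0.1505546002389, 0.5944053964301, 0.3819767923353]
      },
      {
        "l": 0,
        "exponents": 0.6650393875256,
        "coefficients": 1
      },
      {
        "l": 0,
        "exponents": 0.14792,
        "coefficients": 1
      },
      {
        "l": 1,
        "exponents": [10.3544, 2.577706757126, 0.6417148386902],
        "coefficients": [0.0221556534538, 0.1566476115982, 0.8970295569799]
      },
      {
        "l": 1,
        "exponents": 0.1597536,
        "coefficients": 1
      },
      {
        "l": 2,
        "exponents": 0.695224,
        "coefficients": 1
      }
    ],
    "N": [
      {
        "l": 0,
        "exponents": [1690.5782, 371.423397450928, 81.602460137005, 17.928223009406, 3.938866300542],
        "coefficients": [0.004856807756798, 0.02544487918828, 0.15361502609, 0.6042833392368, 0.3699108399687]
      },
      {
        "l": 0,
        "exponents": 0.8653767707713,
        "coefficients": 1
      },
      {
        "l": 0,
        "exponents": 0.190125,
        "coefficients": 1
      },
      {
        "l": 1,
        "exponents": [13.30875, 3.313186162781, 0.8248109363574],
        "coefficients": [0.0221556534538, 0.1566476115982, 0.8970295569799]
      },
      {
        "l": 1,
        "exponents": 0.205335,
        "coefficients": 1
      },
      {
        "l": 2,
        "exponents": 0.8935875,
        "coefficients": 1
      }
    ],
    "O": [
      {
        "l": 0,
        "exponents": [2229.672800000001, 490.633035179882, 107.962376905626, 23.756808024227, 5.22761672794],
        "coefficients": [0.004790347184096, 0.02510369486067, 0.1510556742814, 0.5997390276228, 0.3772318346727]
      },
      {
        "l": 0,
        "exponents": 1.150321904625,
        "coefficients": 1
      },
      {
        "l": 0,
        "exponents": 0.253125,
        "coefficients": 1
      },
      {
        "l": 1,
        "exponents": [17.71875, 4.411046666425, 1.098121069115],
        "coefficients": [0.0221556534538, 0.1566476115982, 0.8970295569799]
      },
      {
        "l": 1,
        "exponents": 0.273375,
        "coefficients": 1
      },
      {
        "l": 2,
        "exponents": 1.1896875,
        "coefficients": 1
      }
    ]
  }
}
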