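name: zebrafish-larva-5mm-synthetic
length: 5.0
stiff_fraction: 0.1
sections:
- s: 0.0
  trunk_y:
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - -0.0
  - -0.0
  - -0.0
  trunk_z:
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
- s: 0.02
  trunk_y:
  - 0.0
  - 0.099
  - 0.14
  - 0.099
  - 0.0
  - -0.099
  - -0.14
  - -0.099
  trunk_z:
  - 0.21
  - 0.1544
  - 0.02
  - -0.1144
  - -0.17
  - -0.1144
  - 0.02
  - 0.1544
- s: 0.06
  trunk_y:
  - 0.0
  - 0.1945
  - 0.275
  - 0.1945
  - 0.0
  - -0.1945
  - -0.275
  - -0.1945
  trunk_z:
  - 0.4
  - 0.2975
  - 0.05
  - -0.1975
  - -0.3
  - -0.1975
  - 0.05
  - 0.2975
- s: 0.08
  trunk_y:
  - 0.0
  - 0.2204
  - 0.3117
  - 0.2204
  - 0.0
  - -0.2204
  - -0.3117
  - -0.2204
  trunk_z:
  - 0.4497
  - 0.3362
  - 0.0622
  - -0.2118
  - -0.3253
  - -0.2118
  - 0.0622
  - 0.3362
  eye:
    a: 0.06
    b: 0.05
    'n': 3.0
    cy: 0.3
    cz: 0.12
- s: 0.12
  trunk_y:
  - 0.0
  - 0.2546
  - 0.36
  - 0.2546
  - 0.0
  - -0.2546
  - -0.36
  - -0.2546
  trunk_z:
  - 0.52
  - 0.3911
  - 0.08
  - -0.2311
  - -0.36
  - -0.2311
  - 0.08
  - 0.3911
  eye:
    a: 0.15
    b: 0.13
    'n': 3.0
    cy: 0.3
    cz: 0.12
- s: 0.16
  trunk_y:
  - 0.0
  - 0.2605
  - 0.3683
  - 0.2605
  - 0.0
  - -0.2605
  - -0.3683
  - -0.2605
  trunk_z:
  - 0.5417
  - 0.408
  - 0.0851
  - -0.2378
  - -0.3716
  - -0.2378
  - 0.0851
  - 0.408
  eye:
    a: 0.18
    b: 0.15
    'n': 3.0
    cy: 0.3
    cz: 0.12
- s: 0.2
  trunk_y:
  - 0.0
  - 0.2475
  - 0.35
  - 0.2475
  - 0.0
  - -0.2475
  - -0.35
  - -0.2475
  trunk_z:
  - 0.53
  - 0.3982
  - 0.08
  - -0.2382
  - -0.37
  - -0.2382
  - 0.08
  - 0.3982
  eye:
    a: 0.1
    b: 0.09
    'n': 3.0
    cy: 0.3
    cz: 0.12
- s: 0.22
  trunk_y:
  - 0.0
  - 0.2379
  - 0.3364
  - 0.2379
  - 0.0
  - -0.2379
  - -0.3364
  - -0.2379
  trunk_z:
  - 0.5181
  - 0.3884
  - 0.0751
  - -0.2383
  - -0.368
  - -0.2383
  - 0.0751
  - 0.3884
  eye:
    a: 0.03
    b: 0.03
    'n': 3.0
    cy: 0.3
    cz: 0.12
- s: 0.3
  trunk_y:
  - 0.0
  - 0.1945
  - 0.275
  - 0.1945
  - 0.0
  - -0.1945
  - -0.275
  - -0.1945
  trunk_z:
  - 0.45
  - 0.3328
  - 0.05
  - -0.2328
  - -0.35
  - -0.2328
  - 0.05
  - 0.3328
- s: 0.35
  trunk_y:
  - 0.0
  - 0.1709
  - 0.2416
  - 0.1709
  - 0.0
  - -0.1709
  - -0.2416
  - -0.1709
  trunk_z:
  - 0.3978
  - 0.2923
  - 0.0375
  - -0.2173
  - -0.3228
  - -0.2173
  - 0.0375
  - 0.2923
  finfold:
    a: 0.03
    b: 0.15
    cz: 0.05
- s: 0.45
  trunk_y:
  - 0.0
  - 0.1344
  - 0.19
  - 0.1344
  - 0.0
  - -0.1344
  - -0.19
  - -0.1344
  trunk_z:
  - 0.295
  - 0.2145
  - 0.02
  - -0.1745
  - -0.255
  - -0.1745
  - 0.02
  - 0.2145
- s: 0.5
  trunk_y:
  - 0.0
  - 0.1192
  - 0.1686
  - 0.1192
  - 0.0
  - -0.1192
  - -0.1686
  - -0.1192
  trunk_z:
  - 0.2534
  - 0.1826
  - 0.012
  - -0.1587
  - -0.2294
  - -0.1587
  - 0.012
  - 0.1826
  finfold:
    a: 0.04
    b: 0.45
    cz: 0.0
- s: 0.6
  trunk_y:
  - 0.0
  - 0.0919
  - 0.13
  - 0.0919
  - 0.0
  - -0.0919
  - -0.13
  - -0.0919
  trunk_z:
  - 0.19
  - 0.1344
  - 0.0
  - -0.1344
  - -0.19
  - -0.1344
  - -0.0
  - 0.1344
- s: 0.65
  trunk_y:
  - 0.0
  - 0.0791
  - 0.1119
  - 0.0791
  - 0.0
  - -0.0791
  - -0.1119
  - -0.0791
  trunk_z:
  - 0.1649
  - 0.1161
  - -0.0016
  - -0.1194
  - -0.1681
  - -0.1194
  - -0.0016
  - 0.1161
  finfold:
    a: 0.04
    b: 0.55
    cz: 0.0
- s: 0.75
  trunk_y:
  - 0.0
  - 0.0566
  - 0.08
  - 0.0566
  - 0.0
  - -0.0566
  - -0.08
  - -0.0566
  trunk_z:
  - 0.12
  - 0.0849
  - 0.0
  - -0.0849
  - -0.12
  - -0.0849
  - -0.0
  - 0.0849
- s: 0.8
  trunk_y:
  - 0.0
  - 0.0476
  - 0.0673
  - 0.0476
  - 0.0
  - -0.0476
  - -0.0673
  - -0.0476
  trunk_z:
  - 0.0974
  - 0.069
  - 0.0004
  - -0.0682
  - -0.0966
  - -0.0682
  - 0.0004
  - 0.069
  finfold:
    a: 0.04
    b: 0.45
    cz: -0.05
- s: 0.9
  trunk_y:
  - 0.0
  - 0.0283
  - 0.04
  - 0.0283
  - 0.0
  - -0.0283
  - -0.04
  - -0.0283
  trunk_z:
  - 0.05
  - 0.0354
  - 0.0
  - -0.0354
  - -0.05
  - -0.0354
  - -0.0
  - 0.0354
- s: 0.95
  trunk_y:
  - 0.0
  - 0.015
  - 0.0212
  - 0.015
  - 0.0
  - -0.015
  - -0.0212
  - -0.015
  trunk_z:
  - 0.0252
  - 0.0178
  - -0.0001
  - -0.0179
  - -0.0253
  - -0.0179
  - -0.0001
  - 0.0178
  finfold:
    a: 0.03
    b: 0.3
    cz: 0.0
- s: 1.0
  trunk_y:
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - -0.0
  - -0.0
  - -0.0
  trunk_z:
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  finfold:
    a: 0.01
    b: 0.05
    cz: 0.0
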