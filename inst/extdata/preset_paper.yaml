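preset: paper
geometry:
  dims:
  - 950
  - 950
  - 2000
  voxelSize: 1.0
  loops:
    x:
    - 550.0
    - 550.0
    - 550.0
    - 700.0
    - 700.0
    - 700.0
    y1:
    - 250.0
    - 450.0
    - 650.0
    - 250.0
    - 450.0
    - 650.0
    y2:
    - 295.0
    - 495.0
    - 695.0
    - 295.0
    - 495.0
    - 695.0
  plexusX:
  - 550.0
  - 700.0
  plexusY:
  - 0.0
  - 950.0
  loopZ:
  - 150.0
  - 300.0
  plexusZ: 300.0
  capDiameter: 10.0
  svpDiameter: 30.0
  sourcePositions:
  - - 250.0
    - 250.0
  - - 250.0
    - 360.0
  crossSectionX: 570.0
layers:
  name:
  - stratum corneum
  - epidermis
  - papillary dermis
  - upper blood net dermis
  - reticular dermis
  - deep blood net dermis
  - subcutaneous tissue
  thickness_um:
  - 20.0
  - 80.0
  - 150.0
  - 80.0
  - 1500.0
  - 100.0
  - 6000.0
media:
  name:
  - stratum corneum
  - epidermis
  - papillary dermis
  - upper blood net dermis
  - reticular dermis
  - deep blood net dermis
  - subcutaneous tissue
  - blood
  mu_a:
  - 1.5
  - 2.5
  - 1.2
  - 1.8
  - 1.0
  - 1.5
  - 0.6
  - 300.0
  mu_s:
  - 60.0
  - 45.0
  - 55.0
  - 60.0
  - 50.0
  - 55.0
  - 35.0
  - 150.0
  g:
  - 0.94
  - 0.88
  - 0.9
  - 0.92
  - 0.87
  - 0.93
  - 0.8
  - 0.99
  'n':
  - 1.5
  - 1.34
  - 1.4
  - 1.39
  - 1.4
  - 1.38
  - 1.44
  - 1.4
source:
  coreDiameter: 20.0
  na: 0.35
detector:
  na: 0.25
  pixelBin: 1
mc:
  nPhotons: 1.0e+10
  rouletteThreshold: 0.01
  rouletteFactor: 10.0
  nExternal: 1.0
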