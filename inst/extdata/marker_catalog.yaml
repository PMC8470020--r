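# Functional marker-gene catalog: each marker symbol resolves to one or more
# annotation identifiers (gene symbols); a marker is present when any alias
# is annotated. The methanogenesis section groups the gene families used by
# the "reverse methanogenesis" presence/absence check: the seven central
# steps of the methanogenic pathway, the canonical hydrogenases of
# methanogens, methylotrophy methyltransferases, dissimilatory nitrate- and
# sulfate-reduction genes, and membrane electron-transfer complexes.
markers:
  mcrA: [mcrA]
  pMMO: [pmoA, pmoB, pmoC]
  dsrAB: [dsrA, dsrB]
  napA: [napA]
  narG: [narG]
  nosZ: [nosZ]
  sox: [soxB, soxY, soxZ]
  soeA: [soeA]
  sqr: [sqr]
  coxA: [coxA]
  ccoN: [ccoN]
  coxL: [coxL, coxM, coxS]
  cooS: [cooS]
  cooF: [cooF]
  Fe-hyd: [hydA]
  hyaB: [hyaB]
  hybC: [hybC]
  GH1: [bglA]
  bzd: [bzdN, bzdO, bzdP, bzdQ]
  PhzF: [phzF]
methanogenesis:
  core_steps:
    fmd: [fmdA, fmdB, fmdC, fmdD, fmdF, fmdG]
    ftr: [ftr]
    mch: [mch]
    mtd: [mtd]
    mer: [mer]
    mtr: [mtrA, mtrB, mtrC, mtrD, mtrE, mtrF, mtrG, mtrH]
    mcr: [mcrA, mcrB, mcrC, mcrG]
  hydrogenases:
    Ech: [echA, echB, echC, echD, echE, echF]
    Vho: [vhoA, vhoC, vhoG]
    Mvh: [mvhA, mvhD, mvhG]
    Frh: [frhA, frhB, frhG]
  methyltransferases:
    mtaB: [mtaB]
    mtbB: [mtbB]
    mtmB: [mtmB]
    mttB: [mttB]
    mdh: [mxaF]
  nitrate_reduction:
    nar: [narG]
    nap: [napA]
    nrf: [nrfA]
    nir: [nirS, nirK]
    nor: [norB]
    nos: [nosZ]
  sulfate_reduction:
    dsrAB: [dsrA, dsrB]
    dsrC: [dsrC]
    qmoA: [qmoA]
    aprAB: [aprA, aprB]
    sat: [sat]
  electron_transfer:
    Fpo: [fpoA, fpoF]
    HdrABC: [hdrA, hdrB, hdrC]
    HdrDE: [hdrD, hdrE]
    Rnf: [rnfA, rnfB, rnfC, rnfD, rnfE, rnfG]
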