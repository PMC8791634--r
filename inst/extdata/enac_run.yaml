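# Example pipeline configuration: the packaged stand-in tree and the verbatim
# published trait coding, one LRT and one ancestry analysis.
tree: synthetic
traits: enac
seed: 1
restarts: 25
lrt:
  - pair: [site1, site2]
    family: pair
  - pair: [site1, terrestrial]
    family: habitat
ancestry:
  - trait: PY
    hypotheses: [unconstrained, divergent, convergent:node1]
    stones: 100
    stone_iters: 10000
outdir: enac_run_output
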