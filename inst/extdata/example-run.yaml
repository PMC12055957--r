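# Reduced-scale cross-slot transit: PC-3-like cell at the experimental flow
# conditions of the 40 um chip.  All lengths in micrometres, SI elsewhere.
geometry:
  kind: cross_slot
  l_um: 40
  corner_r_um: 10
  feed_len_um: 60
  other_len_um: 50
  height_um: 40
  nodes_per_l: 12
fluid:
  K: 0.053
  alpha: 0.95
  mu0: 0.0339
  rho: 1060
cell:
  Ca: 1.0
  C: 10
  eta: 30
  lambda: 1
  confinement: 0.43
  an_over_a: 0.5
run:
  U: 0.17
  d_oc_z: 0.007
  release_x_um: -55
  mesh_subdiv: 3
  mesh_subdiv_nucleus: 2
  max_tstar: 7
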