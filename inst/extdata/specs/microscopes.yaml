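# Microscope configurations used in the benchmarking study, declared from
# their nominal spec-sheet effective magnifications. m_eff values are the
# instruments' quoted magnifications; the lens-train calculus (objective +
# relay + tube objective) is available separately through
# microscope_config() with lens_spec elements.
scmos_8x:          # sCMOS at the common 8x benchmark: 6.5 um / 8 = 812.5 nm
  camera: scmos
  m_eff: 8.0
  na: 1.4
emccd_8x:          # EMCCD at 8x: 16 um / 8 = 2000 nm effective pixels
  camera: emccd
  m_eff: 8.0
  na: 1.4
qis_8x:            # QIS at 8x: 1.1 um / 8 = 137.5 nm effective pixels
  camera: qis
  m_eff: 8.0
  na: 1.4
lv200_emccd_20x:   # 100x oil objective (NA 1.45) + 5x-reducing tube lens
  camera: emccd
  m_eff: 20.0
  na: 1.45
qiscope_2.6x:      # 40x oil objective (NA 1.4) + Keplerian relay + 20x tube objective
  camera: qis
  m_eff: 2.6
  na: 1.4
qiscope_6.5x:      # higher-resolution variant: 100x oil objective (NA 1.45)
  camera: qis
  m_eff: 6.5
  na: 1.45
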