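# Detector spec sheets. Units are in the key names. Values are taken from
# public manufacturer data sheets for the three detector classes compared
# throughout the package; the QIS area is the manufacturer-stated 20.25 mm2
# (recorded as authoritative because the exact active pixel count of the
# 16 MP part is not public).
scmos:
  name: "sCMOS (ORCA-Fusion-BT class)"
  pitch_um: 6.5
  pixels_x: 2304
  pixels_y: 2304
  qe: 0.85
  read_noise_e: 1.0
  dark_e_s: 0.2
  em_gain: 1
  full_well_e: 15000
  adc_gain_e_dn: 0.5
  adc_offset_dn: 100
  bit_depth: 16
  photon_number_resolving: false
emccd:
  name: "EMCCD (iXon-897 class)"
  pitch_um: 16.0
  pixels_x: 512
  pixels_y: 512
  qe: 0.90
  read_noise_e: 45.0
  dark_e_s: 0.001
  em_gain: 300
  full_well_e: 800000       # gain-register capacity, the multiplied-signal limit
  adc_gain_e_dn: 12.0
  adc_offset_dn: 100
  bit_depth: 16
  photon_number_resolving: false
qis:
  name: "QIS (QIS16TS class)"
  pitch_um: 1.1
  pixels_x: 4096
  pixels_y: 4096
  qe: 0.87
  read_noise_e: 0.19
  dark_e_s: 0.066
  em_gain: 1
  full_well_e: 4000
  adc_gain_e_dn: 1.0
  adc_offset_dn: 0
  bit_depth: 16
  photon_number_resolving: true
  sensor_area_mm2: 20.25
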