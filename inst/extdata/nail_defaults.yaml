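# Default nail design parameters.
#
# Published design facts: the PFNA-II carries a 5 degree mediolateral bend,
# a 16.5 mm proximal diameter and a flattened lateral proximal face; the
# older PFNA a 6 degree bend and 17 mm proximal diameter; the InterTan a
# trapezoidal proximal cross-section housing two integrated cephalocervical
# screws. All remaining dimensions (lengths, distal diameters, bend station,
# head-element geometry, trapezoid depth) are not published alongside those
# facts and are shipped here as representative vendor-class values; every
# pipeline run records the values it actually used in its manifest.
pfna2:
  total_length: 200
  proximal_diameter: 16.5
  distal_diameter: 10
  bend_angle: 5
  bend_station: 90
  bend_radius: 50
  ccd_angle: 130
  proximal_section: flat_lateral
  flat_depth: 2.0
  trapezoid_ap_depth: 0
  taper_length: 30
  head_element_length: 100
  head_station: 45
  head_envelope_radius: 5.5
  twin_screws: false
pfna:
  total_length: 200
  proximal_diameter: 17
  distal_diameter: 10
  bend_angle: 6
  bend_station: 90
  bend_radius: 50
  ccd_angle: 130
  proximal_section: circular
  flat_depth: 0
  trapezoid_ap_depth: 0
  taper_length: 30
  head_element_length: 100
  head_station: 45
  head_envelope_radius: 5.5
  twin_screws: false
intertan:
  total_length: 200
  proximal_diameter: 16.25
  distal_diameter: 10
  bend_angle: 4
  bend_station: 90
  bend_radius: 50
  ccd_angle: 130
  proximal_section: trapezoidal
  flat_depth: 0
  trapezoid_ap_depth: 15.5
  trapezoid_lateral_ratio: 0.7
  taper_length: 30
  head_element_length: 100
  head_station: 40
  head_envelope_radius: 7.0
  twin_screws: true
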