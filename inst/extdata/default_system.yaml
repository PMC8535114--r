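magnet:
  volume: 9.424777960769379e-07
  magnetization: 1177746.578880025539547
sensor_array:
  nx: ~
  positions:
  - - -0.05
    - -0.05
    - 0.0
  - - -0.03
    - -0.05
    - 0.0
  - - -0.01
    - -0.05
    - 0.0
  - - 0.01
    - -0.05
    - 0.0
  - - 0.03
    - -0.05
    - 0.0
  - - 0.05
    - -0.05
    - 0.0
  - - -0.05
    - -0.03
    - 0.0
  - - -0.03
    - -0.03
    - 0.0
  - - -0.01
    - -0.03
    - 0.0
  - - 0.01
    - -0.03
    - 0.0
  - - 0.03
    - -0.03
    - 0.0
  - - 0.05
    - -0.03
    - 0.0
  - - -0.05
    - -0.01
    - 0.0
  - - -0.03
    - -0.01
    - 0.0
  - - -0.01
    - -0.01
    - 0.0
  - - 0.01
    - -0.01
    - 0.0
  - - 0.03
    - -0.01
    - 0.0
  - - 0.05
    - -0.01
    - 0.0
  - - -0.05
    - 0.01
    - 0.0
  - - -0.03
    - 0.01
    - 0.0
  - - -0.01
    - 0.01
    - 0.0
  - - 0.01
    - 0.01
    - 0.0
  - - 0.03
    - 0.01
    - 0.0
  - - 0.05
    - 0.01
    - 0.0
  - - -0.05
    - 0.03
    - 0.0
  - - -0.03
    - 0.03
    - 0.0
  - - -0.01
    - 0.03
    - 0.0
  - - 0.01
    - 0.03
    - 0.0
  - - 0.03
    - 0.03
    - 0.0
  - - 0.05
    - 0.03
    - 0.0
  - - -0.05
    - 0.05
    - 0.0
  - - -0.03
    - 0.05
    - 0.0
  - - -0.01
    - 0.05
    - 0.0
  - - 0.01
    - 0.05
    - 0.0
  - - 0.03
    - 0.05
    - 0.0
  - - 0.05
    - 0.05
    - 0.0
  sensitivity: 12.5
  range_limit: 0.169
  supply_voltage: 5.0
  adc_bits: 16
coils:
- shape: circular
  center:
  - 0.0
  - 0.0
  - 0.15
  axis:
  - 0.0
  - 0.0
  - 1.0
  turns: 200
  label: helmholtz_z_up
  radius: 0.25
- shape: circular
  center:
  - 0.0
  - 0.0
  - -0.1
  axis:
  - 0.0
  - 0.0
  - 1.0
  turns: 200
  label: helmholtz_z_down
  radius: 0.25
- shape: circular
  center:
  - 0.173205080756888
  - 0.0
  - 0.025
  axis:
  - 1.0
  - 0.0
  - 0.0
  turns: 400
  label: maxwell_x_pos
  radius: 0.2
- shape: circular
  center:
  - -0.173205080756888
  - 0.0
  - 0.025
  axis:
  - -1.0
  - 0.0
  - 0.0
  turns: 400
  label: maxwell_x_neg
  radius: 0.2
- shape: circular
  center:
  - 0.0
  - 0.173205080756888
  - 0.025
  axis:
  - 0.0
  - 1.0
  - 0.0
  turns: 400
  label: maxwell_y_pos
  radius: 0.2
- shape: circular
  center:
  - 0.0
  - -0.173205080756888
  - 0.025
  axis:
  - 0.0
  - -1.0
  - 0.0
  turns: 400
  label: maxwell_y_neg
  radius: 0.2
- shape: rectangular
  center:
  - 0.13
  - 0.0
  - 0.025
  axis:
  - 1.0
  - 0.0
  - 0.0
  turns: 150
  label: rect_x_pos
  half_width: 0.1
  half_height: 0.15
- shape: rectangular
  center:
  - -0.13
  - 0.0
  - 0.025
  axis:
  - 1.0
  - 0.0
  - 0.0
  turns: 150
  label: rect_x_neg
  half_width: 0.1
  half_height: 0.15
- shape: rectangular
  center:
  - 0.0
  - 0.13
  - 0.025
  axis:
  - 0.0
  - 1.0
  - 0.0
  turns: 150
  label: rect_y_pos
  half_width: 0.1
  half_height: 0.15
- shape: rectangular
  center:
  - 0.0
  - -0.13
  - 0.025
  axis:
  - 0.0
  - 1.0
  - 0.0
  turns: 150
  label: rect_y_neg
  half_width: 0.1
  half_height: 0.15
roi:
  xlim:
  - -0.05
  - 0.05
  ylim:
  - -0.05
  - 0.05
  zlim:
  - 0.005
  - 0.045
current_limit: 20.0
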