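segments:
- stimulus_kind: spot_green
  direction: cw
  angular_velocity: 40.0
  start_time: 30.0
  start_angle: 0.0
  n_turns: 2
  elevation: 45.0
  visual_angle: 16.3
- stimulus_kind: spot_green
  direction: ccw
  angular_velocity: 40.0
  start_time: 48.0
  start_angle: 0.0
  n_turns: 2
  elevation: 45.0
  visual_angle: 16.3
- stimulus_kind: spot_uv
  direction: cw
  angular_velocity: 40.0
  start_time: 96.0
  start_angle: 0.0
  n_turns: 2
  elevation: 45.0
  visual_angle: 16.3
- stimulus_kind: spot_uv
  direction: ccw
  angular_velocity: 40.0
  start_time: 114.0
  start_angle: 0.0
  n_turns: 2
  elevation: 45.0
  visual_angle: 16.3
off_intervals:
- - 0.0
  - 30.0
- - 66.0
  - 96.0
- - 132.0
  - 162.0
stationary_intervals: []
exclude_first_rotation: yes
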