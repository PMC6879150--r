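# Ground-plane scenario, probe 2 degrees below the FOE (the condition with
# the 84% mean human flow-parsing gain). Load with read_scene_config().
scene:
  scenario: ground
  self_motion_speed: 5.7
  component_speed_at_probe: 1.0
  depth_range: [0.56, 25.0]
  field_of_view: 40
  duration: 1.0
  frame_rate: 30
  n_points: 300
  eye_height: 0.40
  rng_seed: 7
probe:
  offset_from_foe: [0.0, -2.0]
  object_speed: 2.5
  diameter: 1.0
  onset: 0.0
  offset: 1.0
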