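rois:
- label: streak_1
  row: 0
  col: 26
  height: 3
  width: 9
  group: location_1
- label: streak_2
  row: 3
  col: 26
  height: 3
  width: 9
  group: location_1
- label: streak_3
  row: 56
  col: 26
  height: 3
  width: 9
  group: location_1
- label: streak_4
  row: 59
  col: 26
  height: 3
  width: 9
  group: location_1
- label: streak_5
  row: 3
  col: 30
  height: 3
  width: 9
  group: location_1
- label: streak_6
  row: 56
  col: 30
  height: 3
  width: 9
  group: location_1
- label: dark_1
  row: 0
  col: 28
  height: 3
  width: 7
  group: location_2
- label: dark_2
  row: 3
  col: 28
  height: 3
  width: 7
  group: location_2
- label: dark_3
  row: 56
  col: 28
  height: 3
  width: 7
  group: location_2
- label: dark_4
  row: 59
  col: 28
  height: 3
  width: 7
  group: location_2
- label: dark_5
  row: 0
  col: 31
  height: 3
  width: 7
  group: location_2
- label: dark_6
  row: 3
  col: 31
  height: 3
  width: 7
  group: location_2
- label: dark_7
  row: 56
  col: 31
  height: 3
  width: 7
  group: location_2
- label: dark_8
  row: 59
  col: 31
  height: 3
  width: 7
  group: location_2
- label: background
  row: 28
  col: 8
  height: 3
  width: 7
  group: background
window:
  row: 20
  col: 37
  length: 24
  width: 8
  nProfiles: 23
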