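[
  {
    "plate_id": "D01",
    "kind": "demonstration",
    "target": "shape",
    "axis": "none"
  },
  {
    "plate_id": "D02",
    "kind": "demonstration",
    "target": "shape",
    "axis": "none"
  },
  {
    "plate_id": "D03",
    "kind": "demonstration",
    "target": "shape",
    "axis": "none"
  },
  {
    "plate_id": "D04",
    "kind": "demonstration",
    "target": "no-shape",
    "axis": "none"
  },
  {
    "plate_id": "T01",
    "kind": "test",
    "target": "shape",
    "axis": "red-green"
  },
  {
    "plate_id": "T02",
    "kind": "test",
    "target": "shape",
    "axis": "red-green"
  },
  {
    "plate_id": "T03",
    "kind": "test",
    "target": "shape",
    "axis": "red-green"
  },
  {
    "plate_id": "T04",
    "kind": "test",
    "target": "shape",
    "axis": "red-green"
  },
  {
    "plate_id": "T05",
    "kind": "test",
    "target": "shape",
    "axis": "red-green"
  },
  {
    "plate_id": "T06",
    "kind": "test",
    "target": "shape",
    "axis": "red-green"
  },
  {
    "plate_id": "T07",
    "kind": "test",
    "target": "shape",
    "axis": "red-green"
  },
  {
    "plate_id": "T08",
    "kind": "test",
    "target": "shape",
    "axis": "red-green"
  },
  {
    "plate_id": "T09",
    "kind": "test",
    "target": "shape",
    "axis": "red-green"
  },
  {
    "plate_id": "T10",
    "kind": "test",
    "target": "shape",
    "axis": "red-green"
  },
  {
    "plate_id": "T11",
    "kind": "test",
    "target": "shape",
    "axis": "red-green"
  },
  {
    "plate_id": "T12",
    "kind": "test",
    "target": "shape",
    "axis": "red-green"
  },
  {
    "plate_id": "T13",
    "kind": "test",
    "target": "shape",
    "axis": "red-green"
  },
  {
    "plate_id": "T14",
    "kind": "test",
    "target": "shape",
    "axis": "red-green"
  },
  {
    "plate_id": "T15",
    "kind": "test",
    "target": "shape",
    "axis": "tritan"
  },
  {
    "plate_id": "T16",
    "kind": "test",
    "target": "shape",
    "axis": "tritan"
  },
  {
    "plate_id": "T17",
    "kind": "test",
    "target": "shape",
    "axis": "tritan"
  },
  {
    "plate_id": "T18",
    "kind": "test",
    "target": "shape",
    "axis": "tritan"
  },
  {
    "plate_id": "T19",
    "kind": "test",
    "target": "shape",
    "axis": "tritan"
  },
  {
    "plate_id": "T20",
    "kind": "test",
    "target": "shape",
    "axis": "tritan"
  }
]
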