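{
  "title": "ribospacer pipeline report",
  "required": {
    "annotations": "array",
    "conservation": "object",
    "blocks": "array",
    "indel_events": "array",
    "tree_newick": "string",
    "structures": "array",
    "type_summary": "object",
    "failures": "array",
    "meta": "object"
  }
}
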