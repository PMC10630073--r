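{
  "$comment": "clonetracker per-sample IS record schema, version 1.0. One JSON file per sample. Counts are authoritative; optional raw per-fragment lists are accepted but ignored by the importer.",
  "type": "object",
  "required": ["schema_version", "sample", "clusters"],
  "properties": {
    "schema_version": {"const": "1.0"},
    "sample": {"type": "string", "minLength": 1,
               "description": "Sample UniqueID"},
    "clusters": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["clu_id", "num_aln", "max_aln_score", "seq_len",
                     "weight", "shear", "tag", "combo", "targets",
                     "labels"],
        "properties": {
          "clu_id": {"type": "string", "minLength": 1,
                     "description": "cluster id, unique within the sample"},
          "cons_seq": {"type": "string",
                       "description": "consensus nucleotide sequence"},
          "num_aln": {"type": "integer", "minimum": 0,
                      "description": "must equal targets length when targets given"},
          "max_aln_score": {"type": "number", "minimum": 0,
                            "description": "must equal max of target aln_score"},
          "seq_len": {"type": "integer", "minimum": 0},
          "weight": {"type": "integer", "minimum": 1,
                     "description": "sequencing-read count; >= max(shear, tag)"},
          "shear": {"type": "integer", "minimum": 1,
                    "description": "distinct sonication fragment lengths"},
          "tag": {"type": "integer", "minimum": 1,
                  "description": "distinct UMIs"},
          "combo": {"type": "integer", "minimum": 1,
                    "description": "distinct (UMI, fragment length) pairs"},
          "targets": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["target_id", "chrom", "coordinate", "strand",
                           "centroid", "offset", "aln_score"],
              "properties": {
                "target_id": {"type": "string"},
                "chrom": {"type": "string"},
                "coordinate": {"type": "integer", "minimum": 1},
                "strand": {"enum": ["+", "-", "*"]},
                "centroid": {"type": "integer"},
                "offset": {"type": "integer"},
                "aln_score": {"type": "number", "minimum": 0}
              }
            }
          },
          "labels": {"type": "array", "items": {"type": "string"}}
        }
      }
    }
  }
}
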