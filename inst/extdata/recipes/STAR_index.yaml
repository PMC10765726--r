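name: STAR_index
version: 0.1.0
description: Use STAR command to build genome index for STAR alignment
script: |
  STAR --runMode genomeGenerate --genomeDir STAR_index --genomeFastaFiles {{fasta}} --sjdbGTFfile {{gtf}} --sjdbOverhang {{sjdb_overhang}} --runThreadN {{threads}}
parameters:
- name: fasta
  type: file
  required: true
  description: Genome FASTA
- name: gtf
  type: file
  required: true
  description: Gene annotation GTF
- name: sjdb_overhang
  type: int
  required: false
  default: 100
  description: ''
- name: threads
  type: int
  required: false
  default: 4
  description: ''
outputs:
- name: index_files
  glob: STAR_index/*
  role: primary
requirements:
- tool: STAR
  version: 2.7.10b
  source: conda-spec
  spec: star=2.7.10b
executable_offline: false
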