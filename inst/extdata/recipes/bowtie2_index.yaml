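name: bowtie2_index
version: 0.1.0
description: Use "bowtie2-build" to index a specific reference genome
script: |
  bowtie2-build --threads {{threads}} {{fasta}} {{basename}}
parameters:
- name: fasta
  type: file
  required: true
  description: Reference genome FASTA
- name: basename
  type: string
  required: true
  description: Index basename
- name: threads
  type: int
  required: false
  default: 4
  description: ''
outputs:
- name: index_files
  glob: '*.bt2'
  role: primary
requirements:
- tool: bowtie2
  version: 2.5.1
  source: conda-spec
  spec: bowtie2=2.5.1
executable_offline: false
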