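name: hisat2_index
version: 0.1.0
description: Use "hisat2-build" to build the index files
script: |
  hisat2-build -p {{threads}} {{fasta}} {{basename}}
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
  glob: '*.ht2'
  role: primary
requirements:
- tool: hisat2
  version: 2.2.1
  source: conda-spec
  spec: hisat2=2.2.1
executable_offline: false
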