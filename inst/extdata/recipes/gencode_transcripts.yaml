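name: gencode_transcripts
version: 0.1.0
description: Download, unzip, and index transcripts files from gencode
origin: https://ftp.ebi.ac.uk/pub/databases/gencode/
script: |
  wget https://ftp.ebi.ac.uk/pub/databases/gencode/Gencode_{{species}}/release_{{version}}/gencode.v{{version}}.transcripts.fa.gz
  gunzip gencode.v{{version}}.transcripts.fa.gz
  samtools faidx gencode.v{{version}}.transcripts.fa
parameters:
- name: species
  type: string
  required: true
  description: human or mouse
- name: version
  type: string
  required: true
  description: GENCODE release
outputs:
- name: fasta
  glob: '*.fa'
  role: primary
- name: index
  glob: '*.fai'
  role: secondary
requirements:
- tool: wget
  version: unversioned
  source: system
  spec: ''
- tool: samtools
  version: '1.17'
  source: conda-spec
  spec: samtools=1.17
executable_offline: false
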