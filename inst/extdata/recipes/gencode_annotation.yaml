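name: gencode_annotation
version: 0.1.0
description: Download and unzip annotation files from gencode
origin: https://ftp.ebi.ac.uk/pub/databases/gencode/
script: |
  wget https://ftp.ebi.ac.uk/pub/databases/gencode/Gencode_{{species}}/release_{{version}}/gencode.v{{version}}.annotation.gtf.gz
  gunzip gencode.v{{version}}.annotation.gtf.gz
parameters:
- name: species
  type: string
  required: true
  description: human or mouse
- name: version
  type: string
  required: true
  description: GENCODE release, e.g. 42
outputs:
- name: gtf
  glob: '*.gtf'
  role: primary
requirements:
- tool: wget
  version: unversioned
  source: system
  spec: ''
executable_offline: false
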