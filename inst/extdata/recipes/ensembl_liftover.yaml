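name: ensembl_liftover
version: 0.1.0
description: Download and unzip genome liftover file from Ensembl
origin: https://ftp.ensembl.org/pub/assembly_mapping/
script: |
  wget https://ftp.ensembl.org/pub/assembly_mapping/{{species}}/{{from}}_to_{{to}}.chain.gz
  gunzip {{from}}_to_{{to}}.chain.gz
parameters:
- name: species
  type: string
  required: true
  description: Species directory name
- name: from
  type: string
  required: true
  description: Source assembly
- name: to
  type: string
  required: true
  description: Target assembly
outputs:
- name: chain
  glob: '*.chain'
  role: primary
requirements:
- tool: wget
  version: unversioned
  source: system
  spec: ''
executable_offline: false
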