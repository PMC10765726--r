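name: ucsc_database
version: 0.1.0
description: Download genome annotation file from UCSC database using the golden path
origin: https://hgdownload.soe.ucsc.edu/goldenPath/
script: |
  wget https://hgdownload.soe.ucsc.edu/goldenPath/{{genome}}/database/{{filename}}
parameters:
- name: genome
  type: string
  required: true
  description: UCSC genome build, e.g. hg38
- name: filename
  type: string
  required: true
  description: Database file name
outputs:
- name: dbfile
  glob: '*'
  role: primary
requirements:
- tool: wget
  version: unversioned
  source: system
  spec: ''
executable_offline: false
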