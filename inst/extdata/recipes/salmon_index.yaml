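name: salmon_index
version: 0.1.0
description: Use "Salmon index" command to build salmon index for your transcriptome
script: |
  salmon index -t {{transcriptome}} -i {{index_name}} -p {{threads}}
parameters:
- name: transcriptome
  type: file
  required: true
  description: Transcriptome FASTA
- name: index_name
  type: string
  required: true
  description: Index directory name
- name: threads
  type: int
  required: false
  default: 4
  description: ''
outputs:
- name: index_files
  glob: '*'
  role: primary
requirements:
- tool: salmon
  version: 1.10.1
  source: conda-spec
  spec: salmon=1.10.1
executable_offline: false
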