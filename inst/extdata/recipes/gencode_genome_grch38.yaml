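name: gencode_genome_grch38
version: 0.1.0
description: Download human genome GRCh38 from GENCODE release 42
origin: https://ftp.ebi.ac.uk/pub/databases/gencode/Gencode_human/release_42/
script: |
  wget https://ftp.ebi.ac.uk/pub/databases/gencode/Gencode_human/release_42/GRCh38.primary_assembly.genome.fa.gz
  gunzip GRCh38.primary_assembly.genome.fa.gz
parameters: []
outputs:
- name: genome
  glob: '*.fa'
  role: primary
requirements:
- tool: wget
  version: unversioned
  source: system
  spec: ''
executable_offline: false
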