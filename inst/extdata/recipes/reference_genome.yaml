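name: reference_genome
version: 0.1.0
description: Download, format and index reference genome file with samtools, picard
  and bwa
script: |
  wget -O genome.fa.gz {{fasta_url}}
  gunzip genome.fa.gz
  samtools faidx genome.fa
  picard CreateSequenceDictionary R=genome.fa O=genome.dict
  bwa index genome.fa
parameters:
- name: fasta_url
  type: string
  required: true
  description: URL of the genome FASTA (gzipped)
outputs:
- name: fasta
  glob: genome.fa
  role: primary
- name: fai
  glob: genome.fa.fai
  role: secondary
- name: dict
  glob: genome.dict
  role: secondary
- name: bwa_index
  glob: genome.fa.*
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
- tool: picard
  version: 3.0.0
  source: conda-spec
  spec: picard=3.0.0
- tool: bwa
  version: 0.7.17
  source: conda-spec
  spec: bwa=0.7.17
executable_offline: false
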