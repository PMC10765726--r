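name: gcp_broad_gatk_hg19
version: 0.1.0
description: Download file in GATK annotation bundle for hg19 from GCP
origin: gs://gcp-public-data--broad-references/hg19/v0/
script: |
  gsutil cp gs://gcp-public-data--broad-references/hg19/v0/{{filename}} .
parameters:
- name: filename
  type: string
  required: true
  description: Bundle file to download
outputs:
- name: bundle_file
  glob: '*'
  role: primary
requirements:
- tool: gsutil
  version: unversioned
  source: conda-spec
  spec: gsutil
executable_offline: false
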