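name: gcp_gatk_mutect2_b37
version: 0.1.0
description: Download file in GATK mutect2 bundle for b37 from GCP
origin: gs://gatk-best-practices/somatic-b37/
script: |
  gsutil cp gs://gatk-best-practices/somatic-b37/{{filename}} .
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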