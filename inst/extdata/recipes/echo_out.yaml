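name: echo_out
version: 0.1.0
description: Print a character string and output as a txt file
script: |
  echo "{{input}}" > {{outfile}}.txt
parameters:
- name: input
  type: string
  required: true
  description: Character string to print
- name: outfile
  type: string
  required: true
  description: Output file basename
outputs:
- name: txt
  glob: '*.txt'
  role: primary
requirements: []
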