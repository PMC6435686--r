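classes:
  AC:
  - SFTPG
  - NAPSA
  - TTF-1
  LCNEC:
  - CHGA
  - SYP
  - CD56
  SqCC:
  - TP73L
  - KRT6A
  - KRT5
  - KRT40
  - KRT16
aliases:
  TTF-1:
  - NKX2-1
  - TTF1
  CD56: NCAM1
  TP73L:
  - TP63
  - P63
  SFTPG: SFTA3
  KRT40: KA36
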