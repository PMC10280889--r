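# Default surgical/medical duty-roster mapping, chapter-group level.
# Reflects a typical split in small/medium hospitals where one on-call team
# covers surgical and one covers medical patients; local policies differ,
# so edit freely. Category-level entries under `categories:` override the
# chapter assignment (e.g. send a single surgically managed category from a
# medical chapter to the surgical team).
chapters:
  "A/B": medical
  C: medical
  D: medical
  E: medical
  F: medical
  G: medical
  H: medical
  I: medical
  J: medical
  K: surgical
  L: medical
  M: surgical
  N: medical
  O: surgical
  P: medical
  Q: medical
  R: medical
  S: surgical
  T: surgical
  U: medical
  V: surgical
  W: surgical
  X: surgical
  Y: surgical
categories: {}
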