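gene	segment
TRBV2	V
TRBV3-1	V
TRBV4-1	V
TRBV4-2	V
TRBV4-3	V
TRBV5-1	V
TRBV5-4	V
TRBV5-5	V
TRBV5-6	V
TRBV5-8	V
TRBV6-1	V
TRBV6-2	V
TRBV6-3	V
TRBV6-4	V
TRBV6-5	V
TRBV6-6	V
TRBV6-8	V
TRBV6-9	V
TRBV7-2	V
TRBV7-3	V
TRBV7-4	V
TRBV7-6	V
TRBV7-7	V
TRBV7-8	V
TRBV7-9	V
TRBV9	V
TRBV10-1	V
TRBV10-2	V
TRBV10-3	V
TRBV11-1	V
TRBV11-2	V
TRBV11-3	V
TRBV12-3	V
TRBV12-4	V
TRBV12-5	V
TRBV13	V
TRBV14	V
TRBV15	V
TRBV16	V
TRBV18	V
TRBV19	V
TRBV20-1	V
TRBV24-1	V
TRBV25-1	V
TRBV27	V
TRBV28	V
TRBV29-1	V
TRBV30	V
TRBJ1-1	J
TRBJ1-2	J
TRBJ1-3	J
TRBJ1-4	J
TRBJ1-5	J
TRBJ1-6	J
TRBJ2-1	J
TRBJ2-2	J
TRBJ2-3	J
TRBJ2-4	J
TRBJ2-5	J
TRBJ2-6	J
TRBJ2-7	J
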