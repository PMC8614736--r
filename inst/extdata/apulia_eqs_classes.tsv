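site_id	season	database	eqs_class
1a	fall	morphological	Moderate
1b	fall	morphological	Poor
1c	fall	morphological	Moderate
2a	fall	morphological	Poor
2b	fall	morphological	Moderate
2c	fall	morphological	Bad
3	fall	morphological	Bad
4	fall	morphological	Poor
5	fall	morphological	Bad
6	fall	morphological	Bad
7a	fall	morphological	Bad
7b	fall	morphological	Poor
8	fall	morphological	Moderate
9	fall	morphological	Poor
10	fall	morphological	High
1a	fall	reduced	Poor
1b	fall	reduced	Bad
1c	fall	reduced	Moderate
2a	fall	reduced	Poor
2b	fall	reduced	Poor
2c	fall	reduced	Bad
3	fall	reduced	Bad
4	fall	reduced	Poor
5	fall	reduced	Bad
6	fall	reduced	Bad
7a	fall	reduced	Bad
7b	fall	reduced	Poor
8	fall	reduced	Bad
9	fall	reduced	Moderate
10	fall	reduced	High
1a	spring	morphological	Poor
1b	spring	morphological	Moderate
1c	spring	morphological	Poor
2a	spring	morphological	Good
2b	spring	morphological	Poor
2c	spring	morphological	Good
3	spring	morphological	Bad
4	spring	morphological	Bad
5	spring	morphological	Bad
6	spring	morphological	Bad
7a	spring	morphological	Bad
7b	spring	morphological	Moderate
8	spring	morphological	Moderate
9	spring	morphological	Moderate
10	spring	morphological	Good
1a	spring	reduced	Poor
1b	spring	reduced	Moderate
1c	spring	reduced	Poor
2a	spring	reduced	Good
2b	spring	reduced	Poor
2c	spring	reduced	Moderate
3	spring	reduced	Bad
4	spring	reduced	Bad
5	spring	reduced	Bad
6	spring	reduced	Bad
7a	spring	reduced	Bad
7b	spring	reduced	Moderate
8	spring	reduced	Moderate
9	spring	reduced	Poor
10	spring	reduced	Moderate
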