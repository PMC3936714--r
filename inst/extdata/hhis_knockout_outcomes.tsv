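set	deleted	outcome
single	oriC1	obtained
single	oriC2	obtained
single	oriC4	obtained
single	oriC5	obtained
single	oriC6	obtained
single	oriC7	obtained
single	oriP	not_obtained
single	cdc6A	obtained_sick
single	cdc6E	obtained
single	cdc6G	obtained
single	cdc6H	obtained
single	cdc6I	obtained
single	cdc6J	obtained
single	cdc6K	not_obtained
multi_origin	oriC1	obtained
multi_origin	oriC2	obtained
multi_origin	oriC1,oriC2	not_obtained
multi_origin	oriC2,oriC1	not_obtained
multi_origin	oriC4,oriC5	obtained
multi_origin	oriC4,oriC5,oriC6	obtained
multi_origin	oriC4,oriC5,oriC7	obtained
multi_origin	oriC6,oriC7	not_obtained
multi_origin	oriC7,oriC6	not_obtained
multi_cdc6	cdc6D,cdc6E	obtained
multi_cdc6	cdc6D,cdc6E,cdc6C	obtained
multi_cdc6	cdc6D,cdc6E,cdc6C,cdc6B	obtained
multi_cdc6	cdc6D,cdc6E,cdc6C,cdc6B,cdc6F	obtained
multi_cdc6	cdc6G,cdc6H	obtained
multi_cdc6	cdc6G,cdc6H,cdc6I	obtained
multi_cdc6	cdc6G,cdc6H,cdc6J	obtained
multi_cdc6	cdc6I,cdc6J	not_obtained
multi_cdc6	cdc6J,cdc6I	not_obtained
multi_cdc6	cdc6D,cdc6E,cdc6C,cdc6B,cdc6F,cdc6G	obtained
multi_cdc6	cdc6D,cdc6E,cdc6C,cdc6B,cdc6F,cdc6G,cdc6H	obtained
multi_cdc6	cdc6D,cdc6E,cdc6C,cdc6B,cdc6F,cdc6G,cdc6H,cdc6J	obtained
multi_cdc6	cdc6D,cdc6E,cdc6C,cdc6B,cdc6F,cdc6G,cdc6H,cdc6I	obtained
titration	oriC2D	not_obtained
titration	oriC1,oriC2D	not_obtained
titration	oriC2,cdc6E,oriC2D	obtained
titration	oriC2,oriC2D	obtained
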