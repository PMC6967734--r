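agent,mac40
isoflurane,1.17
sevoflurane,1.80
desflurane,6.6
nitrous,104
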