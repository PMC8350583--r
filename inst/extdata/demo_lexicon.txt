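# Demonstration category lexicon (word patterns; trailing * = prefix match).
# A small stand-in in the spirit of psycholinguistic word-count categories;
# not a reproduction of any proprietary dictionary.
pronoun: i me my mine myself you your we us our
posemo: love happy hope good nice great joy peace grateful
negemo: sad pain hurt cry fear sorry alone hate guilt
social: friend* family mother father brother sister talk* together
death: death die* dead grave funeral goodbye
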