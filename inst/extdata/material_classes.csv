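# Material-class lookup: first matching pattern (case-insensitive regex) wins.
# Edit or replace to suit your dataset's free-text material vocabulary.
pattern,class
shell|mollus|oyster|cockle,shell
human,bone-human
bone|antler|tooth|tusk,bone-animal
food|crust|residue,food-remains
charcoal|seed|grain|twig|hazel|cereal|nut|bark|plant,short-lived
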