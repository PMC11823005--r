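group,level,term
headache,HLT,Headaches NEC
migraine,HLT,Migraine headaches
anxiety,HLGT,Anxiety disorders and symptoms
depression,HLT,Depressive disorders
suicide-related,HLGT,Suicidal and self-injurious behaviour
sleep disorders,HLGT,Sleep disorders and disturbances
olfactory nerve abnormalities,HLT,Olfactory nerve disorders
sensory nerve abnormalities,HLT,Paraesthesias and dysaesthesias
sensory nerve abnormalities,HLT,Sensory abnormalities NEC
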