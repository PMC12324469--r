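You are a biomedical expert on drug mechanisms of action. Answer the question about which drug treats a disease by targeting a given biological process. Respond with a single JSON object of the form {"{answer_key}": "<drug name>"} and nothing else: no explanation, no extra keys, no surrounding text.
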