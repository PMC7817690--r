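>H2A_canonical
SGRGKQGGKARAKAKTRSSRAGLQFPVGRVHRLLRKGNYAERVGAGAPVYLAAVLEYLTAEILELAGNAARDNKKTRIIPRHLQLAIRNDEELNKLLGKVTIAQGGVLPNIQAVLLPKKTESHHKAKGK
>H2A.B_synthetic
SGR--QGGKARAKAKTRSSRAGLQFPVGQVHRLLRKGNYAERVGAGAPVYLAAVLAYLTAEILELAGNAARDNKKTRIIPRHLQLAIRNDEKLNKLLGKVTIAQGGVLPNIQAV---------------
>TH2A_synthetic
SGRGKQGGKARAKAKSRSSRAGLQFPVGRVHRLLRKGNYAERVGAGAPVYLAAVLEYLTAEILELAGNAARDNKKTRIIPRHLQLAIRNDEELNKLLGRVTIAQGGVLPNIQAVLLPKKTESHHKAKGK
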