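>IgG1-CH3 gene=IGHG1 curated=yes
EPQVYTLPPSRDELTKNQVSLTCLVKGFYPSDIAVEWESNGQPENNYKTTPPVLDSDGSFFLYSKLTVDKSRWQQGNVFSCSVMHEALHNHYTQKSLSLSPGK
>IgG3-CH3 gene=IGHG3 curated=yes
EPQVYTLPPSREEMTKNQVSLTCLVKGFYPSDIAVEWESSGQPENNYKTTPPVLDSDGSFFLYSKLTVDKSRWQQGNIFSCSVMHEALHNRFTQKSLSLSPGK
>TCR-Ca gene=TRAC curated=yes
IQQVYQLRDSKSSDTSNSDKSVCLFTGFDSQTNVSQSKDSDVYITDKYITADVMDFKSNSSAVAWSNKSDFACANAFNNSIIPEDTFFPSPESSCDVKLVESF
>TCR-Cb gene=TRBC1 curated=yes
DLENAVFPPEVAVFEPSKATLVCLATGFFPDHVELSWWVNGKEVHSRKLDSALSENDEWTCQSSRLRVSATFWQNPRNHFRCQVQFYGLSDEWTQDRAKPVTQ
>TCR-Cg gene=TRGC1 curated=yes
DKQLYALDVSPKPTIFLPSETKCLLEGFFPDVIKIHWEEKKSNTILGRSTHQVEDSNGAFYMTSWKEDSKFNCNDTYMKFSWLTVPEKSLDKEHRCIVRHENN
>TCR-Cd gene=TRDC curated=yes
SQPHTKPSVFVMKNGTNSANVACLVEGFYPKDIRINLVSSKKITEFDKPSAVIPSGKYNTCVSEWHSTDFEVKTDSTDHVKPKETENTKQPSKSDHKPKAIVH
>IgA-CH3 gene=IGHA1 curated=yes
PEEHVLLPPSEELALNELVTLTCLARGFSPKDVLVRWLQGSQELPEKRLWASIREPSQGTLTFALTRVAAEDWKKGDTFSCMVGHEALPLAFTQKTIDRLAGK
>IgD-CH3 gene=IGHD curated=yes
PATGFSLPPSQPLSLEELSQATCLVNGHFPEAVNITWKQDGSNQATGSFIPNARNESGDLVHWLEGSQELPQAPWNHGETFTCTVTHPDLPSPQAPGRYFAHS
>IgM-CH4 gene=IGHM curated=yes
PDVYLLPPAREQLNLRESATITCLVTGFSPADVFVQWMQRGQPLSYTSAPMPEPQAPGRYFAHSILTVSEEEWNTGETYTCVVAHEALPNRVTERTVDKSTGK
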