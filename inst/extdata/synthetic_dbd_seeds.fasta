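>DBD_human_syn synthetic 76-aa DBD seed
CVGIIMQGVFADLQNCPSEALIEPIVFERESGNILAMTTQPLAEEPEDTLDYLICPLSNDLNGAMLIFLKFRLGLN
>DBD_worm_syn synthetic 76-aa DBD seed
CVGIIMQGPGADLDNCGIEALIAPIVFERESGNILAMTTVPLAEEPEDTLQYLICPLSNVLNAAMLIFLKFRLGLE
>DBD_fly_syn synthetic 76-aa DBD seed
CVGIIMQGPFADLQNCGIEALIAPIVFERESGNILAMTTVPLAEEPEDTLQYLDCPFSNDLNAAMLIFLKFRLGLN
>DBD_yeast_syn synthetic 76-aa DBD seed
CVTIIMQGPFSDLQNCGIEALISPTVFEYEKGNIVAMTTVPLAEEPEATLQYLICPLSNDLNAAMLIFLKFRLGLN
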