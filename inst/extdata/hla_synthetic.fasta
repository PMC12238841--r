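>HLA-A*02:01
KYNTTWIDRIIAMMCVGFEMMWMFLHAWQTEFCKWFLNLCPPNIVHDPYIPNCNWAFWMGDAHYCWKYMCFTSVNSVHCM
YYEHWHSAWQDSWPFSGIWQAYWLILPLGGWCGWIKSCKDPCCISFGIYRQFPHHTQWSFIEGIEFYWHEPIIPFQYEHC
RRTVFLHKWLNYDADDVTTTWEGSMHTKQW
>HLA-A*01:01
TGCIEEFRNKRYSVKPTVGDNRCWSWHQCKYPKWAYKMDWVYFFKFKIDRNIIGPVCVKCPDVPHRLTYHVWEYMGFKFF
DVNPPCFMIMTQYPKSREMAISYVPFIEKCASTCVGTEDHPLQKDCVTEIAENKPKCAHHLASNMFCQSIGHNDVYQINK
INIHDIVCLHTNIPLAWYMKYGDGWDWCKT
>HLA-A*24:02
YPAWGSHFWHYDHLNIWPNAWCKLICSVHQNDMLIMQRHAPTPMYVVLAVMGMTKDEHFMICLRYFWLKSCPKYQEKYHF
MFYCRLVWCKRYTCDIKPYCIVTRLLCWHTIRQDFKPDWDSCDGKKYCISIECFGWVFMECTRKVKEESTRQNMWDCNAR
QDDAGTIRCASLQHDPCMYMSMGRTGWTLK
>HLA-A*03:01
ERFVSYCCDRDQFGSFDGVNSFDHMFHHWEKANPDGWCNGNPCWPQMYGCWFDELVLFFCEQWATHVVFRVLTYFFIEIT
FAFSRTHVMCIQECCTTEYVHVDQHRRYVMIVMCVCEFIRKSKDMLDQANNDKGMLWDTEPTVNQVADWIDHHSYCYFPW
THKIVWHPWTTGAKDVRVCLPWTFNDESEM
>HLA-C*07:02
WLGQDRKMPKCAFYLAWSINWPGQSELSQWKCDYPPHDNNQAATNWLSHELNRMDNNTVRTVELMMNTSDFMDAFWSRNA
PHFKNKESCPWEGSKVRGRSKRELPHICSWMWYDPNQLWYVDFLAQRFYYMTDPMEICYWQILANSSFWSCQSFSNWAKL
PNWRKKKEWIQMTSSSKMQGMQAWRKWRIM
>HLA-C*04:01
TAIELKNHYDMIYCGFTGYSQFACIMRAPGDQPMMSCRLNIEEDSAPVGDISDSIKHYFMDPMKSHWRYSFEPEYGELVN
LMNRYYSYRMMWMNNLGACICYKFYMFERVYSTCMGNFDFGVYGAVTVGIMAVHVTINAVQRMVRMNTGMSFNIGRAGGD
DHVVWALWQRFEMKWQFYSRLNIAYDTMYK
>HLA-C*07:01
ACFDDGNRCINKQIAFAIMGEQCFNMTIFDFPAHMPPMQVHMWECRTDTGTRTCSDMPVGRWCKKWGQFVNWAWWYVPYH
FPKSQMCKHHHEYCHGQEMSYLCQFEEMSYWQSSVSHFKRINIIIVYVMKDSVTVMCCFYPLSPEHPHHNIFQILEPKDW
TLHMCCAPMGCYELAFQIHKWNHHECNVFT
>HLA-A*11:01
LYDWQPKAINVWNCEFVAHYTHPGCDEMGFLLCWDSTSYSFPTVMAAGMRQIEFQCKATVWQFMGDEMQVLLDTKWRTGK
EELEYTCMGIYPQSYVGHILYKQNNHEVYRAQMVGFVQKEFNEMMVIYCCWGTAYTMPSQGCWRSLTMYTICKFGCNTRT
LCIMVVSFVEIHQHLNWMCEMMVFYPEQWF
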